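#' Write a dataset as delimited text with a YAML sidecar
#'
#' Score matrices (or accuracy + response-time pairs) are stored as wide CSV
#' with a `person` identifier column and one column per item; missing entries
#' are written as `NA`. A small self-describing YAML sidecar records the
#' provenance: dataset type, deadline, number of speed bins and the boundary
#' convention, so any derived artifact can be reproduced from the files alone.
#'
#' @param x a score matrix, or a list with `accuracy`, `rt`, `deadline` as
#'   produced by [simulate_continuous_srt()].
#' @param path CSV path for the (score or accuracy) matrix. For response data
#'   the RT matrix is written next to it with suffix `_rt.csv`.
#' @param sidecar path of the YAML sidecar; default `paste0(path, ".yaml")`.
#' @param provenance optional named list merged into the sidecar (e.g. the
#'   `"provenance"` attribute of [score_responses()]).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, sidecar = paste0(path, ".yaml"),
                          provenance = NULL) {
  meta <- provenance %||% attr(x, "provenance") %||% list()
  as_tb <- function(m) {
    tb <- tibble::as_tibble(as.data.frame(m))
    names(tb) <- colnames(m) %||% paste0("item", seq_len(ncol(m)))
    dplyr::bind_cols(tibble::tibble(person = rownames(m) %||%
                                      as.character(seq_len(nrow(m)))), tb)
  }
  if (is.list(x) && !is.data.frame(x)) {
    readr::write_csv(as_tb(x$accuracy), path, na = "NA")
    rt_path <- sub("\\.csv$", "_rt.csv", path)
    readr::write_csv(as_tb(x$rt), rt_path, na = "NA")
    meta$type <- "response"
    meta$deadline <- x$deadline
    meta$rt_file <- basename(rt_path)
  } else {
    readr::write_csv(as_tb(as.matrix(x)), path, na = "NA")
    meta$type <- meta$type %||% "scores"
  }
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates on read: cells must parse as numbers or `NA`; response times may
#' not exceed the deadline (violations are rejected naming the offending
#' cell); persons or items with no observations are dropped with a warning.
#'
#' @param path CSV path.
#' @param sidecar YAML sidecar path; default `paste0(path, ".yaml")`.
#' @return A list of class `dsrt_dataset`: either `scores` or
#'   `accuracy` + `rt` + `deadline`, plus `person_id`, `item_id`, and the
#'   sidecar metadata as `provenance`.
#' @export
read_dataset <- function(path, sidecar = paste0(path, ".yaml")) {
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list(type = "scores")
  read_mat <- function(p) {
    tb <- readr::read_csv(p, show_col_types = FALSE, na = c("", "NA"))
    if (!"person" %in% names(tb)) abort(sprintf("%s: missing `person` column.", p))
    ids <- as.character(tb$person)
    if (anyDuplicated(ids)) {
      abort(sprintf("%s: duplicated person identifier(s): %s.", p,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    if (anyDuplicated(setdiff(names(tb), "person"))) {
      abort(sprintf("%s: duplicated item identifiers.", p))
    }
    m <- as.matrix(tb[setdiff(names(tb), "person")])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(m, 2L, as.numeric))) & !is.na(m),
                   arr.ind = TRUE)[1L, ]
      abort(sprintf("%s: malformed cell at person %s, item %s.",
                    p, ids[bad[1L]], colnames(m)[bad[2L]]))
    }
    rownames(m) <- ids
    m
  }
  if (identical(meta$type, "response")) {
    acc <- read_mat(path)
    rt <- read_mat(file.path(dirname(path), meta$rt_file))
    d <- meta$deadline
    if (is.null(d)) abort("Sidecar must supply `deadline` for response data.")
    over <- which(!is.na(rt) & rt > d, arr.ind = TRUE)
    if (nrow(over)) {
      abort(sprintf("RT exceeds the deadline (%g) at person %s, item %s.",
                    d, rownames(rt)[over[1L, 1L]], colnames(rt)[over[1L, 2L]]))
    }
    out <- list(accuracy = acc, rt = rt, deadline = d)
    obs <- !is.na(acc)
  } else {
    scores <- read_mat(path)
    out <- list(scores = scores)
    obs <- !is.na(scores)
  }
  drop_p <- rowSums(obs) == 0L
  drop_i <- colSums(obs) == 0L
  if (any(drop_p) || any(drop_i)) {
    warn(sprintf("Dropping %d person(s) and %d item(s) with no observations.",
                 sum(drop_p), sum(drop_i)))
    out <- lapply(out, function(m) {
      if (is.matrix(m)) m[!drop_p, !drop_i, drop = FALSE] else m
    })
  }
  m1 <- out[[1L]]
  structure(c(out, list(person_id = rownames(m1), item_id = colnames(m1),
                        provenance = meta)),
            class = "dsrt_dataset")
}

#' @export
print.dsrt_dataset <- function(x, ...) {
  kind <- if (!is.null(x$scores)) "scores" else
    sprintf("accuracy + rt (deadline %g s)", x$deadline)
  cat(sprintf("<dsrt_dataset> %s: %d persons x %d items\n",
              kind, length(x$person_id), length(x$item_id)))
  invisible(x)
}
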