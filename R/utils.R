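#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @useDynLib dsrt, .registration = TRUE
NULL

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax of a matrix of logits, numerically stabilized.
softmax_rows <- function(l) {
  m <- apply(l, 1L, max)
  e <- exp(l - m)
  e / rowSums(e)
}

#' Deterministic child seed derivation
#'
#' One master seed drives a whole study; every condition and replication gets
#' its own reproducible child seed so that any single replication can be re-run
#' in isolation. The scheme is a fixed affine map modulo a prime below 2^31.
#'
#' @param master integer master seed.
#' @param stream integer stream identifier (e.g. condition index).
#' @param index integer index within the stream (e.g. replication number).
#' @return A single integer usable with [set.seed()].
#' @export
child_seed <- function(master, stream = 0L, index = 0L) {
  m <- as.double(master %% 1000003L)
  s <- (m * 20011 + as.double(stream) * 100003 + as.double(index) * 7919 + 12345)
  as.integer(s %% 2147483587) + 1L
}

# Coerce persons x items input (matrix or data frame, possibly with an id
# column) to an integer matrix with NA for missing, plus person/item ids.
as_score_matrix <- function(data, n_categories = NULL) {
  person_id <- NULL
  if (is.data.frame(data)) {
    idcol <- intersect(c("person", "person_id", "id"), names(data))
    if (length(idcol)) {
      person_id <- as.character(data[[idcol[1L]]])
      data <- data[setdiff(names(data), idcol)]
    }
    data <- as.matrix(data)
  }
  if (!is.matrix(data)) abort("`data` must be a matrix or data frame of item scores.")
  storage.mode(data) <- "double"
  if (any(data[!is.na(data)] %% 1 != 0)) {
    abort("Item scores must be integers (category codes starting at 0).")
  }
  x <- matrix(as.integer(data), nrow(data), ncol(data),
              dimnames = dimnames(data))
  if (is.null(person_id)) {
    person_id <- if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x)))
  }
  item_id <- if (!is.null(colnames(x))) colnames(x) else paste0("item", seq_len(ncol(x)))
  C <- n_categories %||% (max(x, na.rm = TRUE) + 1L)
  if (any(x[!is.na(x)] < 0L | x[!is.na(x)] >= C)) {
    abort(sprintf("Scores must lie in 0..%d.", C - 1L))
  }
  list(scores = x, person_id = person_id, item_id = item_id, n_categories = as.integer(C))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -1 encodes missing for the compiled kernels
scores_for_cpp <- function(x) {
  x[is.na(x)] <- -1L
  storage.mode(x) <- "integer"
  x
}
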