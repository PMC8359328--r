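# Internal model-family abstraction.
#
# Every fitted variant is described by a family object giving, per item:
#   logprob(par, Theta) -> C x Q log category probabilities at node matrix Theta
#   mstep(par, counts, Theta, iter) -> updated working-scale parameters
# plus parameter bookkeeping (working scale uses log slopes so positivity
# constraints disappear). All softmax-linear members share one Newton update;
# the IRTree family decomposes its M-step into three binary logistic blocks.

WORK_LO <- -6   # log-slope box: alpha in [e^-6, e^4]
WORK_HI <- 4

clamp_par <- function(par, is_slope) {
  par[is_slope] <- pmin(pmax(par[is_slope], WORK_LO), WORK_HI)
  par[!is_slope] <- pmin(pmax(par[!is_slope], -30), 30)
  par
}

# column maxima of a small-row matrix without apply() overhead
col_max <- function(l) {
  m <- l[1L, ]
  for (i in seq_len(nrow(l))[-1L]) m <- pmax(m, l[i, ])
  m
}

softmax_logprob <- function(l) {
  C <- nrow(l)
  m <- col_max(l)
  lz <- m + log(.colSums(exp(l - rep(m, each = C)), C, ncol(l)))
  l - rep(lz, each = C)
}

softmax_objective <- function(l, counts, Nhat) {
  C <- nrow(l)
  m <- col_max(l)
  lz <- m + log(.colSums(exp(l - rep(m, each = C)), C, ncol(l)))
  sum(counts * l) - sum(Nhat * lz)
}

# One-to-three damped Newton steps on the weighted multinomial log-likelihood
# sum_cq counts[c,q] log softmax_c(logits(par)[, q]).
newton_softmax <- function(par, counts, Theta, logits_fn, design_fn, curv,
                           iter = 2L) {
  P <- length(par)
  C <- nrow(counts); Q <- ncol(counts)
  Nhat <- .colSums(counts, C, Q)
  obj0 <- softmax_objective(logits_fn(par, Theta), counts, Nhat)
  for (it in seq_len(iter)) {
    l <- logits_fn(par, Theta)
    m <- col_max(l)
    e <- exp(l - rep(m, each = C))
    Pm <- e / rep(.colSums(e, C, Q), each = C)
    Rm <- counts - Pm * rep(Nhat, each = C)
    D <- design_fn(par, Theta)
    Dl <- lapply(seq_len(P), function(p) D[, , p])
    grad <- numeric(P)
    Mq <- matrix(0, Q, P)
    for (p in seq_len(P)) {
      grad[p] <- sum(Rm * Dl[[p]])
      Mq[, p] <- .colSums(Pm * Dl[[p]], C, Q)
    }
    H <- matrix(0, P, P)
    for (p1 in seq_len(P)) for (p2 in p1:P) {
      h <- -sum(Nhat * .colSums(Pm * Dl[[p1]] * Dl[[p2]], C, Q)) +
        sum(Nhat * Mq[, p1] * Mq[, p2])
      H[p1, p2] <- H[p2, p1] <- h
    }
    # exact curvature of log-slope parameters: d2 logit / du2 = d logit / du
    for (p in which(curv)) H[p, p] <- H[p, p] + grad[p]
    step <- tryCatch(solve(-H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- tryCatch(solve(-H + diag(1e-4 + abs(diag(H)) * 1e-6, P), grad),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
    }
    t_len <- 1
    improved <- FALSE
    for (h in 1:12) {
      cand <- clamp_par(par + t_len * step, curv)
      obj1 <- softmax_objective(logits_fn(cand, Theta), counts, Nhat)
      if (is.finite(obj1) && obj1 >= obj0 - 1e-10) {
        par <- cand; obj0 <- obj1; improved <- TRUE; break
      }
      t_len <- t_len / 2
    }
    if (!improved) break
  }
  par
}

.design_cache <- new.env(parent = emptyenv())

indicator_design <- function(C, Q, cats) {
  # C x Q x length(cats) array of category indicators (constant over nodes)
  key <- paste(C, Q, paste(cats, collapse = ","))
  hit <- .design_cache[[key]]
  if (!is.null(hit)) return(hit)
  D <- array(0, c(C, Q, length(cats)))
  for (j in seq_along(cats)) D[cats[j] + 1L, , j] <- 1
  .design_cache[[key]] <- D
  D
}

make_family <- function(model, C = 4L,
                        c1 = seq_len(C) - 1, c2 = NULL) {
  model <- match.arg(model, c("coomans", "pcm", "srt1d", "nrm", "srt2d",
                              "hm", "irtree"))
  if (is.null(c2)) {
    c2 <- if (C == 4L) c(1, 0, 0, 1) else {
      nb <- C / 2L                      # symmetric speed loading, fastest high
      ts <- decode_scores(seq_len(C) - 1L, nb)$t_star
      ts
    }
  }
  if (length(c1) != C || length(c2) != C) {
    abort(sprintf("Scoring vectors must have length %d.", C))
  }
  K1 <- C - 1L
  cats <- seq_len(K1)              # categories with free intercepts
  bmat <- function(b, Q) matrix(c(0, b), C, Q)

  fam <- switch(model,
    coomans = list(
      ndim = 1L, npar = 1L, curv = FALSE, par_names = "delta",
      logits = function(par, Theta) outer(c1, Theta[, 1L] - par[1L]),
      design = function(par, Theta) array(-c1, c(C, nrow(Theta), 1L)),
      init = function(freq) c(delta = 0),
      n_params = function(K) K,
      to_natural = function(par) tibble::tibble(delta = par[, 1L]),
      from_natural = function(tb) cbind(tb$delta)
    ),
    pcm = list(
      ndim = 1L, npar = K1, curv = rep(FALSE, K1),
      par_names = paste0("beta", cats),
      logits = function(par, Theta) outer(c1, Theta[, 1L]) + bmat(par, nrow(Theta)),
      design = function(par, Theta) indicator_design(C, nrow(Theta), cats),
      init = function(freq) log(freq[-1L] / freq[1L]),
      n_params = function(K) K * K1,
      to_natural = function(par) {
        tb <- tibble::as_tibble(par, .name_repair = "minimal")
        names(tb) <- paste0("beta", cats); tb
      },
      from_natural = function(tb) as.matrix(tb[paste0("beta", cats)])
    ),
    srt1d = list(
      ndim = 1L, npar = 1L + K1, curv = c(TRUE, rep(FALSE, K1)),
      par_names = c("log_alpha", paste0("beta", cats)),
      logits = function(par, Theta) {
        outer(c1, exp(par[1L]) * Theta[, 1L]) + bmat(par[-1L], nrow(Theta))
      },
      design = function(par, Theta) {
        Q <- nrow(Theta)
        D <- array(0, c(C, Q, 1L + K1))
        D[, , 1L] <- outer(c1, exp(par[1L]) * Theta[, 1L])
        D[, , -1L] <- indicator_design(C, Q, cats)
        D
      },
      init = function(freq) c(0, log(freq[-1L] / freq[1L])),
      n_params = function(K) K * (1L + K1),
      to_natural = function(par) {
        tb <- tibble::tibble(alpha = exp(par[, 1L]))
        for (j in cats) tb[[paste0("beta", j)]] <- par[, 1L + j]
        tb
      },
      from_natural = function(tb) {
        cbind(log(tb$alpha), as.matrix(tb[paste0("beta", cats)]))
      }
    ),
    nrm = list(
      ndim = 1L, npar = 2L * K1, curv = rep(FALSE, 2L * K1),
      par_names = c(paste0("a", cats), paste0("beta", cats)),
      logits = function(par, Theta) {
        rbind(0, outer(par[seq_len(K1)], Theta[, 1L])) + bmat(par[K1 + cats], nrow(Theta))
      },
      design = function(par, Theta) {
        Q <- nrow(Theta)
        D <- array(0, c(C, Q, 2L * K1))
        for (j in cats) D[j + 1L, , j] <- Theta[, 1L]
        D[, , K1 + cats] <- indicator_design(C, Q, cats)
        D
      },
      init = function(freq) c(seq_len(K1) * 0.5, log(freq[-1L] / freq[1L])),
      n_params = function(K) K * 2L * K1,
      to_natural = function(par) {
        tb <- tibble::as_tibble(par, .name_repair = "minimal")
        names(tb) <- c(paste0("a", cats), paste0("beta", cats)); tb
      },
      from_natural = function(tb) as.matrix(tb[c(paste0("a", cats), paste0("beta", cats))])
    ),
    srt2d = list(
      ndim = 2L, npar = 2L + K1, curv = c(TRUE, TRUE, rep(FALSE, K1)),
      par_names = c("log_alpha1", "log_alpha2", paste0("beta", cats)),
      uses_rho = TRUE,
      logits = function(par, Theta) {
        outer(c1, exp(par[1L]) * Theta[, 1L]) +
          outer(c2, exp(par[2L]) * Theta[, 2L]) + bmat(par[-(1:2)], nrow(Theta))
      },
      design = function(par, Theta) {
        Q <- nrow(Theta)
        D <- array(0, c(C, Q, 2L + K1))
        D[, , 1L] <- outer(c1, exp(par[1L]) * Theta[, 1L])
        D[, , 2L] <- outer(c2, exp(par[2L]) * Theta[, 2L])
        D[, , -(1:2)] <- indicator_design(C, Q, cats)
        D
      },
      init = function(freq) c(0, 0, log(freq[-1L] / freq[1L])),
      n_params = function(K) K * (2L + K1) + 1L,
      to_natural = function(par) {
        tb <- tibble::tibble(alpha1 = exp(par[, 1L]), alpha2 = exp(par[, 2L]))
        for (j in cats) tb[[paste0("beta", j)]] <- par[, 2L + j]
        tb
      },
      from_natural = function(tb) {
        cbind(log(tb$alpha1), log(tb$alpha2), as.matrix(tb[paste0("beta", cats)]))
      }
    ),
    hm = local({
      if (C != 4L) abort("The hierarchical model requires 4 joint categories.")
      xv <- c(0, 0, 1, 1); fv <- c(1, 0, 0, 1)
      list(
        ndim = 2L, npar = 4L, curv = c(TRUE, FALSE, TRUE, FALSE),
        par_names = c("log_alpha_acc", "beta_acc", "log_alpha_spd", "beta_spd"),
        uses_rho = TRUE,
        logits = function(par, Theta) {
          outer(xv, exp(par[1L]) * Theta[, 1L] + par[2L]) +
            outer(fv, exp(par[3L]) * Theta[, 2L] + par[4L])
        },
        design = function(par, Theta) {
          Q <- nrow(Theta)
          D <- array(0, c(C, Q, 4L))
          D[, , 1L] <- outer(xv, exp(par[1L]) * Theta[, 1L])
          D[, , 2L] <- matrix(xv, C, Q)
          D[, , 3L] <- outer(fv, exp(par[3L]) * Theta[, 2L])
          D[, , 4L] <- matrix(fv, C, Q)
          D
        },
        init = function(freq) {
          px <- sum(freq[3:4]); pf <- sum(freq[c(1L, 4L)])
          c(0, log(px / (1 - px)), 0, log(pf / (1 - pf)))
        },
        n_params = function(K) K * 4L + 1L,
        to_natural = function(par) tibble::tibble(
          alpha_acc = exp(par[, 1L]), beta_acc = par[, 2L],
          alpha_spd = exp(par[, 3L]), beta_spd = par[, 4L]
        ),
        from_natural = function(tb) {
          cbind(log(tb$alpha_acc), tb$beta_acc, log(tb$alpha_spd), tb$beta_spd)
        }
      )
    }),
    irtree = local({
      if (C != 4L) abort("The IRTree model requires 4 joint categories.")
      # score coding: 0 = fast wrong, 1 = slow wrong, 2 = slow right, 3 = fast right
      list(
        ndim = 2L, npar = 6L,
        curv = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
        par_names = c("log_alpha_spd", "beta_spd", "log_alpha_fast", "beta_fast",
                      "log_alpha_slow", "beta_slow"),
        uses_rho = TRUE, irtree = TRUE,
        logits = NULL,
        logprob = function(par, Theta) {
          u <- exp(par[1L]) * Theta[, 2L] + par[2L]   # fast-branch logit
          vf <- exp(par[3L]) * Theta[, 1L] + par[4L]  # accuracy | fast
          vs <- exp(par[5L]) * Theta[, 1L] + par[6L]  # accuracy | slow
          lpf <- -log1p(exp(-u)); lps <- -log1p(exp(u))
          rbind(lpf - log1p(exp(vf)),    # fast, incorrect
                lps - log1p(exp(vs)),    # slow, incorrect
                lps - log1p(exp(-vs)),   # slow, correct
                lpf - log1p(exp(-vf)))   # fast, correct
        },
        init = function(freq) {
          pf <- sum(freq[c(1L, 4L)])
          pxf <- freq[4L] / pf; pxs <- freq[3L] / sum(freq[2:3])
          c(0, log(pf / (1 - pf)), 0, log(pxf / (1 - pxf)), 0, log(pxs / (1 - pxs)))
        },
        n_params = function(K) K * 6L + 1L,
        to_natural = function(par) tibble::tibble(
          alpha_spd = exp(par[, 1L]), beta_spd = par[, 2L],
          alpha_fast = exp(par[, 3L]), beta_fast = par[, 4L],
          alpha_slow = exp(par[, 5L]), beta_slow = par[, 6L]
        ),
        from_natural = function(tb) {
          cbind(log(tb$alpha_spd), tb$beta_spd, log(tb$alpha_fast), tb$beta_fast,
                log(tb$alpha_slow), tb$beta_slow)
        }
      )
    })
  )
  fam$model <- model
  fam$C <- C
  fam$c1 <- c1
  fam$c2 <- c2
  fam$uses_rho <- isTRUE(fam$uses_rho)
  if (is.null(fam$logprob)) {
    fam$logprob <- function(par, Theta) softmax_logprob(fam$logits(par, Theta))
  }
  if (is.null(fam$mstep)) {
    if (isTRUE(fam$irtree)) {
      fam$mstep <- irtree_mstep
    } else {
      fam$mstep <- function(par, counts, Theta, iter = 2L) {
        newton_softmax(par, counts, Theta, fam$logits, fam$design, fam$curv, iter)
      }
    }
  }
  fam
}

# Binary logistic Newton update used by the IRTree branches: counts2 is a
# 2 x Q matrix (failure row first), z the relevant node coordinate. Closed-form
# 2 x 2 Newton with step halving; slope is exp(par2[1]).
binary_logistic_update <- function(par2, counts2, z, iter = 2L) {
  n1 <- counts2[2L, ]; n <- n1 + counts2[1L, ]
  obj <- function(p) {
    eta <- exp(p[1L]) * z + p[2L]
    sum(n1 * stats::plogis(eta, log.p = TRUE) +
          counts2[1L, ] * stats::plogis(-eta, log.p = TRUE))
  }
  obj0 <- obj(par2)
  for (it in seq_len(iter)) {
    az <- exp(par2[1L]) * z
    eta <- az + par2[2L]
    pr <- stats::plogis(eta)
    r <- n1 - n * pr
    w <- n * pr * (1 - pr)
    g <- c(sum(r * az), sum(r))
    H11 <- -sum(w * az * az) + g[1L]      # log-slope curvature term
    H12 <- -sum(w * az); H22 <- -sum(w)
    det <- H11 * H22 - H12 * H12
    if (!is.finite(det) || abs(det) < 1e-12) break
    step <- c(H22 * g[1L] - H12 * g[2L], H11 * g[2L] - H12 * g[1L]) / -det
    if (any(!is.finite(step))) break
    t_len <- 1; improved <- FALSE
    for (h in 1:12) {
      cand <- clamp_par(par2 + t_len * step, c(TRUE, FALSE))
      obj1 <- obj(cand)
      if (is.finite(obj1) && obj1 >= obj0 - 1e-10) {
        par2 <- cand; obj0 <- obj1; improved <- TRUE; break
      }
      t_len <- t_len / 2
    }
    if (!improved) break
  }
  par2
}

irtree_mstep <- function(par, counts, Theta, iter = 2L) {
  spd <- binary_logistic_update(par[1:2],
                                rbind(counts[2L, ] + counts[3L, ],
                                      counts[1L, ] + counts[4L, ]),
                                Theta[, 2L], iter)
  fst <- binary_logistic_update(par[3:4],
                                rbind(counts[1L, ], counts[4L, ]),
                                Theta[, 1L], iter)
  slw <- binary_logistic_update(par[5:6],
                                rbind(counts[2L, ], counts[3L, ]),
                                Theta[, 1L], iter)
  c(spd, fst, slw)
}

model_n_categories <- function(model, default = 4L) {
  if (model %in% c("hm", "irtree")) 4L else default
}
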