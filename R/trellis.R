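## Soft-information trellis decoding ------------------------------------------
##
## The decoder runs on the trellis whose state is the four most recently
## emitted bases (256 states once the read is under way).  Each transition
## appends one base and emits the two-base color against the previous base;
## every fifth step additionally emits the second-stream color for the
## completed 5-base block.  Observations enter through per-color error
## probabilities: an observed color equals the emitted one with probability
## 1 - eps and is otherwise uniform over the three wrong colors.

#' Observation model for soft decoding
#'
#' Per-color error probabilities, either given directly or derived from
#' Phred qualities as `eps = 10^(-Q/10)`.  Probabilities are clamped to
#' (1e-10, 1 - 1e-10) so log-likelihoods stay finite.
#'
#' @param qualities integer Phred qualities, one per color (stream order
#'   then ECC order) or a single value recycled to all colors.
#' @param epsilon alternatively, the error probabilities themselves.
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(qualities = NULL, epsilon = NULL) {
  if (is.null(epsilon)) {
    if (is.null(qualities)) {
      stop("supply either qualities or epsilon", call. = FALSE)
    }
    epsilon <- 10^(-as.numeric(qualities) / 10)
  }
  epsilon <- pmin(pmax(as.numeric(epsilon), 1e-10), 1 - 1e-10)
  structure(list(eps = epsilon), class = "observation_model")
}

# Predicted second-stream color for state s (digits b_(j-4)..b_(j-1), coded
# base-4 with the oldest base in the highest digit) extended by base b.
.ecc_pred_table <- function(probe) {
  s <- 0:255
  w <- cbind(s %/% 64L, (s %/% 16L) %% 4L, (s %/% 4L) %% 4L, s %% 4L)
  p <- as.integer(probe)
  tab <- matrix(0L, 256L, 4L)
  for (b in 0:3) {
    acc <- .GF4_MUL[p[5L] * 4L + b + 1L]
    acc <- rep.int(acc, 256L)
    for (j in 1:4) {
      if (p[j] != 0L) acc <- bitwXor(acc, .GF4_MUL[p[j] * 4L + w[, j] + 1L])
    }
    tab[, b + 1L] <- acc
  }
  tab
}

# Per-observation log-likelihood lookup: returns log P(obs | emitted) for
# emitted = 0..3.  Missing observations contribute a flat likelihood.
.obs_loglik <- function(obs, eps) {
  if (is.na(obs)) return(rep(log(0.25), 4L))
  out <- rep(log(eps / 3), 4L)
  out[obs + 1L] <- log1p(-eps)
  out
}

.expand_eps <- function(model, n) {
  eps <- model$eps
  if (length(eps) == 1L) eps <- rep(eps, n)
  if (length(eps) != n) {
    stop(sprintf("observation model has %d error probabilities but the read has %d colors",
                 length(eps), n), call. = FALSE)
  }
  eps
}

.trellis_check <- function(read, code, model) {
  if (length(read$color_stream) != code$k) {
    stop(sprintf("read has %d colors but code expects k = %d",
                 length(read$color_stream), code$k), call. = FALSE)
  }
  model <- if (is.null(model)) {
    if (is.null(read$qualities)) {
      stop("no observation model: supply `model` or a read with qualities",
           call. = FALSE)
    }
    observation_model(read$qualities)
  } else model
  list(model = model, eps = .expand_eps(model, code$n))
}

#' Maximum-likelihood (Viterbi) decoding of a color-space read
#'
#' Finds the base sequence maximising the joint likelihood of all observed
#' colors (two-base stream and punctured second stream) over all `4^k`
#' candidate sequences, by dynamic programming on the 256-state trellis.
#' Ties are broken deterministically towards the lexicographically smaller
#' sequence (base order A < C < G < T).
#'
#' @param read an `observed_read` (missing calls allowed).
#' @param code the matching [ecc_code()].
#' @param model an [observation_model()]; defaults to one built from the
#'   read's qualities.
#' @return A list of class `viterbi_decoded` with `bases` (integer GF(4)
#'   vector) and `loglik` (the maximised joint log-likelihood).
#' @export
viterbi_decode <- function(read, code, model = NULL) {
  ck <- .trellis_check(read, code, model)
  eps <- ck$eps
  k <- code$k
  ecc_tab <- .ecc_pred_table(code$probe)
  ll2 <- lapply(seq_len(k), function(j) .obs_loglik(read$color_stream[j], eps[j]))
  lle <- lapply(seq_len(code$m),
                function(i) .obs_loglik(read$ecc_stream[i], eps[k + i]))
  # log-likelihood of the step-(j+1) emissions for state s (time j) and base b
  step_ll <- function(j1, s, b) {
    prev <- if (j1 == 1L) code$adapter else s %% 4L
    out <- ll2[[j1]][bitwXor(prev, b) + 1L]
    if (j1 %% 5L == 0L) {
      out <- out + lle[[j1 %/% 5L]][ecc_tab[cbind(s + 1L, b + 1L)] + 1L]
    }
    out
  }
  ## backward pass: beta[[j]][s + 1] = best achievable log-likelihood of the
  ## emissions after step j, given state s at time j
  beta <- vector("list", k)
  beta[[k]] <- numeric(4L^min(k, 4L))
  for (j in rev(seq_len(k - 1L))) {
    S <- 4L^min(j, 4L)
    s <- 0:(S - 1L)
    bj <- rep(-Inf, S)
    for (b in 0:3) {
      succ <- if (j >= 4L) (s %% 64L) * 4L + b else s * 4L + b
      bj <- pmax(bj, step_ll(j + 1L, s, rep.int(b, S)) + beta[[j + 1L]][succ + 1L])
    }
    beta[[j]] <- bj
  }
  total <- max(vapply(0:3, function(b) {
    step_ll(1L, 0L, b) + beta[[1L]][b + 1L]
  }, numeric(1)))
  ## forward greedy reconstruction: at each step take the smallest base that
  ## still admits an optimal completion -- the lexicographically smallest
  ## maximum-likelihood sequence (base order A < C < G < T)
  tol <- 1e-9
  bases <- integer(k)
  s <- 0L
  acc <- 0
  for (j in seq_len(k)) {
    for (b in 0:3) {
      succ <- if (j > 4L) (s %% 64L) * 4L + b else s * 4L + b
      val <- acc + step_ll(j, s, b) + beta[[j]][succ + 1L]
      if (val >= total - tol) {
        bases[j] <- b
        acc <- acc + step_ll(j, s, b)
        s <- succ
        break
      }
    }
  }
  structure(list(bases = bases, loglik = acc), class = "viterbi_decoded")
}

#' @export
print.viterbi_decoded <- function(x, ...) {
  cat("<Viterbi decoding>\n  bases:  ", gf4_to_bases(x$bases),
      sprintf("\n  loglik: %.4f\n", x$loglik), sep = "")
  invisible(x)
}

#' Per-position posterior (forward-backward) decoding
#'
#' Computes, for each read position, the exact marginal posterior over the
#' four bases given all observed colors, assuming a uniform prior over
#' source sequences, via the scaled forward-backward algorithm on the same
#' trellis as [viterbi_decode()].  The called base is the posterior
#' argmax (ties towards A < C < G < T) and its quality the Phred-scaled
#' probability that the call is wrong.
#'
#' @inheritParams viterbi_decode
#' @return An object of class `posterior_call`: a list with `posterior`
#'   (`k` x 4 matrix, columns A, C, G, T; rows sum to 1), `bases` (integer
#'   GF(4) vector of argmax calls) and `quality` (integer Phred score per
#'   call, capped at 60).
#' @export
posterior_decode <- function(read, code, model = NULL) {
  ck <- .trellis_check(read, code, model)
  eps <- ck$eps
  k <- code$k
  ecc_tab <- .ecc_pred_table(code$probe)
  obs_s <- read$color_stream
  obs_e <- read$ecc_stream
  lik2 <- lapply(seq_len(k), function(j) exp(.obs_loglik(obs_s[j], eps[j])))
  like <- lapply(seq_len(code$m),
                 function(i) exp(.obs_loglik(obs_e[i], eps[k + i])))

  ## forward
  alpha <- vector("list", k)
  a <- 1
  for (j in seq_len(k)) {
    l2 <- lik2[[j]]
    if (j == 1L) {
      anew <- a * l2[bitwXor(code$adapter, 0:3) + 1L]
    } else if (j <= 4L) {
      S <- 4L^j
      sp <- 0:(S - 1L)
      pred <- sp %/% 4L
      b <- sp %% 4L
      anew <- a[pred + 1L] * l2[bitwXor(pred %% 4L, b) + 1L]
    } else {
      sp <- 0:255
      b <- sp %% 4L
      hi <- sp %/% 4L
      emit2 <- l2[bitwXor(hi %% 4L, b) + 1L]
      ecc_step <- j %% 5L == 0L
      if (ecc_step) le <- like[[j %/% 5L]]
      anew <- numeric(256L)
      for (d in 0:3) {
        predidx <- d * 64L + hi + 1L
        contrib <- a[predidx] * emit2
        if (ecc_step) contrib <- contrib * le[ecc_tab[cbind(predidx, b + 1L)] + 1L]
        anew <- anew + contrib
      }
    }
    anew <- anew / sum(anew)
    alpha[[j]] <- anew
    a <- anew
  }

  ## backward
  beta <- vector("list", k)
  beta[[k]] <- rep(1, length(alpha[[k]]))
  for (j in rev(seq_len(k - 1L))) {
    S <- 4L^min(j, 4L)
    s <- 0:(S - 1L)
    l2 <- lik2[[j + 1L]]
    bnext <- beta[[j + 1L]]
    ecc_step <- (j + 1L) %% 5L == 0L
    if (ecc_step) le <- like[[(j + 1L) %/% 5L]]
    bj <- numeric(S)
    for (b in 0:3) {
      succ <- if (j >= 4L) (s %% 64L) * 4L + b else s * 4L + b
      lik <- l2[bitwXor(s %% 4L, b) + 1L]
      if (ecc_step) lik <- lik * le[ecc_tab[s + 1L, b + 1L] + 1L]
      bj <- bj + lik * bnext[succ + 1L]
    }
    beta[[j]] <- bj / sum(bj)
  }

  posterior <- matrix(0, k, 4L, dimnames = list(NULL, .GF4_BASE))
  for (j in seq_len(k)) {
    gamma <- alpha[[j]] * beta[[j]]
    last <- (seq_along(gamma) - 1L) %% 4L
    for (b in 0:3) posterior[j, b + 1L] <- sum(gamma[last == b])
    posterior[j, ] <- posterior[j, ] / sum(posterior[j, ])
  }
  bases <- max.col(posterior, ties.method = "first") - 1L
  pmax_ <- posterior[cbind(seq_len(k), bases + 1L)]
  structure(list(posterior = posterior, bases = bases,
                 quality = posterior_to_phred(pmax_)),
            class = "posterior_call")
}

#' @export
print.posterior_call <- function(x, ...) {
  cat("<posterior calls>\n  bases:   ", gf4_to_bases(x$bases),
      "\n  quality: ", paste(x$quality, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Phred-scale the confidence of a posterior call
#'
#' @param p_max numeric vector of winning posterior probabilities.
#' @param cap maximum reported quality (default 60).
#' @return Integer qualities `round(-10 log10(1 - p_max))`, capped.
#' @examples
#' posterior_to_phred(0.9)   # 10
#' posterior_to_phred(0.25)  # 1
#' @export
posterior_to_phred <- function(p_max, cap = 60L) {
  stopifnot(all(p_max >= 0 & p_max <= 1))
  q <- round(-10 * log10(pmax(1 - p_max, 1e-300)))
  as.integer(pmin(q, cap))
}
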