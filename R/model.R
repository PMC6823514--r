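## Nucleotide substitution models (HKY, GTR) and transition matrices.
## Base order throughout: A, C, G, T.

BASES <- c("A", "C", "G", "T")

#' Nucleotide substitution models
#'
#' Reversible rate matrices for sequence simulation, scaled so one unit of
#' branch length equals one expected substitution per site at equilibrium.
#' `hky_model()` has a single transition/transversion ratio `kappa`;
#' `gtr_model()` takes the six exchangeabilities in the order AC, AG, AT,
#' CG, CT, GT.
#'
#' @param kappa transition/transversion rate ratio (HKY).
#' @param freq equilibrium base frequencies (A, C, G, T), summing to 1.
#' @param rates six GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @return object of class `subst_model` with elements `model_id`, `Q`
#'   (scaled rate matrix), `freq`, and the eigendecomposition used by
#'   [transition_matrix()].
#' @export
hky_model <- function(kappa = 2, freq = rep(0.25, 4)) {
  r <- c(1, kappa, 1, 1, kappa, 1)  # AC AG AT CG CT GT
  build_model("HKY", r, freq)
}

#' @rdname hky_model
#' @export
gtr_model <- function(rates = rep(1, 6), freq = rep(0.25, 4)) {
  stopifnot(length(rates) == 6, all(rates > 0))
  build_model("GTR", rates, freq)
}

build_model <- function(id, rates, freq) {
  stopifnot(length(freq) == 4, all(freq > 0))
  if (abs(sum(freq) - 1) > 1e-12) stop("frequencies must sum to 1")
  R <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  R[upper.tri(R)] <- rates[c(1, 2, 4, 3, 5, 6)]  # column-major upper triangle
  R <- R + t(R)
  Q <- R %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))   # expected rate at equilibrium
  Q <- Q / scale
  dimnames(Q) <- list(BASES, BASES)
  ## symmetrized eigendecomposition: B = D^1/2 Q D^-1/2 is symmetric for
  ## reversible Q, so the decomposition is exact and stable
  s <- sqrt(freq)
  B <- diag(s) %*% Q %*% diag(1 / s)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(model_id = id, Q = Q, freq = freq,
                 evec = diag(1 / s) %*% eg$vectors,
                 ivec = t(eg$vectors) %*% diag(s),
                 eval = eg$values),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(x$model_id, "model, frequencies", paste(format(x$freq), collapse = " "), "\n")
  print(round(x$Q, 4))
  invisible(x)
}

#' Transition probability matrix exp(Q t)
#'
#' @param model a [hky_model()] or [gtr_model()].
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 4x4 row-stochastic matrix, rows = parent base, cols = child base.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop("negative branch length")
  P <- model$evec %*% (exp(model$eval * t) * model$ivec)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}
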