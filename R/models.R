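#' Discrete-gamma rate multipliers
#'
#' Equal-probability discretisation of a Gamma(shape, rate = shape)
#' distribution (mean 1) using the category means, the dominant
#' convention in maximum-likelihood phylogenetics.
#'
#' @param alpha gamma shape (> 0); small values = strong rate
#'   heterogeneity across sites.
#' @param k number of categories (default 4).
#' @return numeric vector of `k` rate multipliers averaging 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (alpha <= 0) stopf("gamma shape must be positive")
  k <- as.integer(k)
  if (k < 1L) stopf("need at least one rate category")
  if (k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X; X in (b_i, b_{i+1})] via the incomplete-gamma identity for mean-1 gamma
  cum <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  k * diff(cum)
}

#' Build a reversible substitution model
#'
#' Constructs a time-reversible rate matrix Q = S diag(pi), rescaled so
#' the expected substitution rate at equilibrium is one per unit branch
#' length, with discrete-gamma rate heterogeneity across sites.
#' The empirical amino-acid exchangeabilities (WAG, LG) are taken from
#' the phangorn distribution of those published matrices.
#'
#' @param name `"poisson"` (equal amino-acid exchangeabilities),
#'   `"wag"`, `"lg"`, or `"gtr-like"` (nucleotide general
#'   time-reversible).
#' @param pi equilibrium frequencies: a probability vector in model
#'   state order, `"model-default"` (uniform for poisson/gtr-like, the
#'   matrix authors' frequencies for WAG/LG), or `"empirical"` (counted
#'   from `data`).
#' @param alpha gamma shape for among-site rate variation.
#' @param n_categories number of discrete gamma categories.
#' @param exchangeabilities optional symmetric matrix (or, for
#'   `"gtr-like"`, the 6-vector AC,AG,AT,CG,CT,GT) overriding the named
#'   matrix.
#' @param data alignment used when `pi = "empirical"`.
#' @return object of class `subst_model` with elements `alphabet`,
#'   `states`, `S`, `pi`, `Q`, `alpha`, `rates`, and an eigensystem used
#'   to exponentiate Q.
#' @export
build_model <- function(name = c("poisson", "wag", "lg", "gtr-like"),
                        pi = "model-default", alpha = 1, n_categories = 4L,
                        exchangeabilities = NULL, data = NULL) {
  name <- match.arg(name)
  alphabet <- if (name == "gtr-like") "dna" else "aa"
  states <- model_states(alphabet)
  n <- length(states)

  S <- matrix(1, n, n)
  default_pi <- rep(1 / n, n)
  if (name %in% c("wag", "lg")) {
    obj <- get(paste0(".", toupper(name)), envir = asNamespace("phangorn"))
    S <- matrix(0, n, n)
    S[lower.tri(S)] <- obj$Q
    S <- S + t(S)
    default_pi <- unname(obj$bf)
  }
  if (!is.null(exchangeabilities)) {
    ex <- exchangeabilities
    if (name == "gtr-like" && !is.matrix(ex)) {
      if (length(ex) != 6L) stopf("gtr-like needs 6 exchangeabilities")
      S <- matrix(0, 4, 4)
      # column-wise lower triangle = AC, AG, AT, CG, CT, GT
      S[lower.tri(S)] <- ex
      S <- S + t(S)
    } else {
      if (!isTRUE(all.equal(ex, t(ex)))) stopf("exchangeabilities must be symmetric")
      S <- ex
    }
  }
  diag(S) <- 0
  if (any(S < 0)) stopf("exchangeabilities must be nonnegative")

  if (is.character(pi)) {
    pi <- match.arg(pi, c("model-default", "empirical"))
    pi <- if (pi == "model-default") default_pi
          else empirical_frequencies(data, alphabet)
  }
  if (length(pi) != n) stopf("pi must have %d entries", n)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stopf("pi must be a probability vector summing to 1")
  pi <- pi / sum(pi)

  finalize_model(alphabet, states, S, pi, alpha, n_categories, name)
}

empirical_frequencies <- function(data, alphabet) {
  if (is.null(data)) stopf("pi = \"empirical\" requires data")
  m <- if (inherits(data, "phylo_alignment")) data$matrix else data
  states <- model_states(alphabet)
  cnt <- table(factor(as.vector(m), levels = states))
  if (sum(cnt) == 0) stopf("no countable residues for empirical frequencies")
  as.vector(cnt / sum(cnt))
}

# assemble Q, rescale to one expected substitution per unit length, and
# eigendecompose through the pi-symmetrised form (real spectrum)
finalize_model <- function(alphabet, states, S, pi, alpha, k, name) {
  n <- length(states)
  Q <- S * rep(pi, each = n)        # Q_ij = S_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stopf("degenerate model: zero total rate")
  Q <- Q / mu

  sp <- sqrt(pi)
  ok <- pi > 0
  B <- Q * (sp / rep(ifelse(ok, sp, 1), each = n))  # diag(sp) Q diag(1/sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  U <- e$vectors / sp               # diag(1/sp) %*% V
  Uinv <- t(e$vectors) * rep(sp, each = n)  # t(V) %*% diag(sp)

  structure(list(name = name, alphabet = alphabet, states = states,
                 S = S, pi = pi, Q = Q, alpha = alpha,
                 n_categories = as.integer(k),
                 rates = discrete_gamma_rates(alpha, k),
                 eig = list(values = e$values, U = U, Uinv = Uinv)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model '%s' (%s, %d states), alpha = %g, %d gamma categories\n",
              x$name, x$alphabet, length(x$states), x$alpha, x$n_categories))
  invisible(x)
}

#' Transition probability matrix P = exp(Q t r)
#'
#' @param model a [build_model()] object.
#' @param t branch length (expected substitutions per site at rate 1).
#' @param rate rate multiplier (e.g. a discrete-gamma category mean).
#' @return row-stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stopf("branch length must be nonnegative")
  if (rate <= 0) stopf("rate multiplier must be positive")
  e <- model$eig
  P <- e$U %*% (exp(e$values * t * rate) * e$Uinv)
  # clip eigen-roundoff; magnitudes are ~1e-16 and do not disturb reversibility
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}
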