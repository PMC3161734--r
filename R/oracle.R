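#' Brute-force elementary flux mode enumeration (reference implementation)
#'
#' Independent of the double description engine: every support subset T of
#' the reaction set is tested directly against the definition. T carries an
#' elementary mode iff the kernel of the internal stoichiometric matrix
#' restricted to T is one-dimensional with a kernel vector that is nonzero on
#' all of T (which implies no proper subset of T admits a steady-state flux)
#' and sign-feasible on the irreversible reactions. A fully reversible
#' support yields one mode per orientation, matching [enumerate_efms()].
#' Exponential in the number of reactions; intended for networks with at
#' most ~16 reactions as a test oracle.
#'
#' @param net A [metabolic_network()].
#' @param tol Relative tolerance for rank and nonzero decisions.
#' @return An `efm_set` with canonical integer modes.
#' @export
enumerate_efms_bruteforce <- function(net, tol = 1e-8) {
  S <- stoich_matrix(net, internal_only = TRUE)
  n <- ncol(S)
  if (n > 20L) stop("brute-force oracle limited to 20 reactions")
  rev <- vapply(net$reactions, function(r) r$reversible, logical(1))
  modes <- list()
  for (mask in seq_len(2^n - 1)) {
    T <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    A <- S[, T, drop = FALSE]
    sv <- svd(A, nu = 0, nv = ncol(A))
    rk <- sum(sv$d > tol * max(sv$d, 1))
    if (length(T) - rk != 1L) next
    v <- if (length(T) == 1L) 1 else sv$v[, length(T)]
    if (any(abs(v) < tol * max(abs(v)))) next  # kernel vector must be fully nonzero
    full <- numeric(n)
    for (orient in c(1, -1)) {
      w <- orient * v
      irr <- !rev[T]
      if (any(w[irr] < 0)) next
      if (!any(irr) && orient == -1 && all(rev[T])) {
        # fully reversible support: both orientations are distinct modes
      }
      full[] <- 0
      full[T] <- w
      modes[[length(modes) + 1L]] <- integerize_vector(full)
    }
  }
  V <- if (length(modes)) do.call(cbind, modes) else matrix(0, n, 0)
  rownames(V) <- names(net$reactions)
  V <- V[, !duplicated(efm_keys(V)), drop = FALSE]
  V <- V[, order_modes(V), drop = FALSE]
  colnames(V) <- if (ncol(V)) paste0("efm", seq_len(ncol(V))) else character(0)
  structure(list(network = net, modes = V,
                 meta = list(algorithm = "brute force subset oracle",
                             elapsed = NA_real_, cap = Inf)),
            class = "efm_set")
}

# Scale a real kernel vector to the smallest integer vector (gcd 1).
integerize_vector <- function(v, tol = 1e-6, max_den = 2000L) {
  nz <- abs(v) > 0
  v <- v / min(abs(v[nz]))
  for (k in seq_len(max_den)) {
    kv <- k * v
    if (all(abs(kv - round(kv)) < tol)) {
      iv <- round(kv)
      g <- Reduce(gcd_int, abs(iv[iv != 0]))
      return(iv / g)
    }
  }
  stop("could not rationalise kernel vector")
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}
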