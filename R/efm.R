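#' Enumerate all elementary flux modes of a network
#'
#' An elementary flux mode (EFM) is a steady-state flux vector (S v = 0 over
#' the internal metabolites) with minimal support that respects the
#' irreversibility constraints. Enumeration splits every reversible reaction
#' into a forward/backward pair, computes the extreme rays of the resulting
#' pointed cone by the double description method (iterative hyperplane
#' intersection with a combinatorial adjacency test, rows processed by
#' ascending nonzero count), discards the spurious forward/backward
#' two-cycles, and un-splits. Arithmetic is exact (64-bit integers with
#' 128-bit intermediates), so the returned modes satisfy S v = 0 exactly and
#' each is the smallest integer vector of its ray (gcd 1). Reversible
#' reactions used backwards carry negative flux on the original reaction; a
#' mode whose support is fully reversible appears once per feasible
#' orientation.
#'
#' @param net A [metabolic_network()] with at least one internal metabolite.
#' @param cap Abort if the number of intermediate rays exceeds this count
#'   (guards runaway inputs; the default accommodates the largest mode
#'   classes reported for curated nitrogen-metabolism models).
#' @return An object of class `efm_set`: list with `network`, `modes` (an
#'   integer-valued matrix, rows = reactions in declaration order, columns =
#'   modes in canonical support order) and `meta` (elapsed time, algorithm
#'   statistics).
#' @export
enumerate_efms <- function(net, cap = 5e6) {
  stopifnot(inherits(net, "metabolic_network"))
  S <- stoich_matrix(net, internal_only = TRUE)
  if (nrow(S) == 0L) stop("network has no internal metabolites")
  Sint <- integerize_rows(S)
  rev <- vapply(net$reactions, function(r) r$reversible, logical(1))
  n <- ncol(Sint)
  Ssplit <- cbind(Sint, -Sint[, rev, drop = FALSE])
  storage.mode(Ssplit) <- "integer"
  t0 <- proc.time()[["elapsed"]]
  Vsplit <- .dd_enumerate(Ssplit, cap)
  elapsed <- proc.time()[["elapsed"]] - t0
  V <- Vsplit[seq_len(n), , drop = FALSE]
  if (any(rev))
    V[which(rev), ] <- V[which(rev), , drop = FALSE] -
      Vsplit[n + seq_len(sum(rev)), , drop = FALSE]
  keep <- colSums(abs(V)) > 0  # drop split-pair two-cycles (zero net flux)
  V <- V[, keep, drop = FALSE]
  rownames(V) <- names(net$reactions)
  V <- V[, order_modes(V), drop = FALSE]
  colnames(V) <- if (ncol(V)) paste0("efm", seq_len(ncol(V))) else character(0)
  structure(
    list(network = net, modes = V,
         meta = list(elapsed = elapsed, n_split_rays = ncol(Vsplit),
                     n_two_cycles = sum(!keep), algorithm = "double description",
                     cap = cap)),
    class = "efm_set")
}

# Scale each row to integers (clears rational coefficients such as 1/2).
integerize_rows <- function(S) {
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    if (all(abs(row - round(row)) < 1e-9)) { S[i, ] <- round(row); next }
    done <- FALSE
    for (q in 2:10000) {
      if (all(abs(row * q - round(row * q)) < 1e-7)) {
        S[i, ] <- round(row * q); done <- TRUE; break
      }
    }
    if (!done) stop("could not scale stoichiometric row ", rownames(S)[i],
                    " to integers")
  }
  S
}

# Deterministic canonical order: by support pattern, then flux values.
order_modes <- function(V) {
  if (ncol(V) == 0L) return(integer(0))
  keys <- vapply(seq_len(ncol(V)), function(k) {
    v <- V[, k]
    nz <- which(v != 0)
    paste(sprintf("%04d%+.0f", nz, v[nz]), collapse = "|")
  }, character(1))
  order(keys)
}

#' @export
print.efm_set <- function(x, ...) {
  cat(sprintf("<efm_set> %d modes over %d reactions (%s, %.2fs)\n",
              ncol(x$modes), nrow(x$modes), x$meta$algorithm,
              x$meta$elapsed %||% NA_real_))
  invisible(x)
}

#' Number of modes in an EFM set
#' @param efms An `efm_set`.
#' @return Integer count.
#' @export
n_modes <- function(efms) ncol(efms$modes)

#' Extract one flux mode
#'
#' @param efms An `efm_set`.
#' @param i Mode index.
#' @return A `flux_mode`: list with `fluxes` (named vector over reactions),
#'   `support` (reaction ids with nonzero flux) and `overall` (net
#'   external-metabolite equation, see [overall_equation()]).
#' @export
efm_mode <- function(efms, i) {
  v <- efms$modes[, i]
  structure(
    list(fluxes = v, support = names(v)[v != 0],
         overall = overall_equation(v, efms$network)),
    class = "flux_mode")
}

#' Overall external-metabolite equation of a mode
#'
#' Multiplying the external rows of the stoichiometric matrix by the flux
#' vector cancels all internal metabolites exactly and leaves the net
#' consumption (negative) and production (positive) of each external
#' metabolite -- the overall chemical equation of the mode, from which carbon
#' yields are computed.
#'
#' @param mode Named flux vector over the reactions of `net`, or a
#'   `flux_mode`.
#' @param net The [metabolic_network()] the mode belongs to.
#' @return Named numeric vector over external metabolites with nonzero net
#'   coefficient.
#' @export
overall_equation <- function(mode, net) {
  if (inherits(mode, "flux_mode")) mode <- mode$fluxes
  Sext <- stoich_matrix(net, internal_only = FALSE)
  Sext <- Sext[net$metabolites$is_external, , drop = FALSE]
  ov <- drop(Sext %*% mode[colnames(Sext)])
  ov[ov != 0]
}

# External-by-mode matrix of overall equations for a whole set.
overall_matrix <- function(efms) {
  Sfull <- stoich_matrix(efms$network, internal_only = FALSE)
  Sext <- Sfull[efms$network$metabolites$is_external, , drop = FALSE]
  Sext %*% efms$modes
}

subset_efms <- function(efms, keep) {
  efms$modes <- efms$modes[, keep, drop = FALSE]
  efms
}

#' Select the modes that synthesise a target from a carbon source
#'
#' Keeps modes with strictly positive net production of `target` and strictly
#' negative net consumption of at least one designated carbon source. CO2 is
#' never a designated carbon source: yields below one correspond to net CO2
#' release, above one to non-photosynthetic CO2 incorporation.
#'
#' @param efms An `efm_set`.
#' @param target External metabolite id (typically an amino acid).
#' @param carbon_sources Character vector of external carbon-source ids;
#'   defaults to the network configuration.
#' @return The filtered `efm_set`.
#' @export
classify_by_target <- function(efms, target, carbon_sources = NULL) {
  net <- efms$network
  carbon_sources <- carbon_sources %||% net$config$carbon_sources
  if (is.null(carbon_sources) || length(carbon_sources) == 0L)
    stop("no carbon sources given and none in the network configuration")
  ext <- net$metabolites$id[net$metabolites$is_external]
  if (!target %in% ext) stop("target '", target, "' is not an external metabolite")
  OV <- overall_matrix(efms)
  produces <- OV[target, ] > 0
  src <- intersect(carbon_sources, rownames(OV))
  consumes <- colSums(OV[src, , drop = FALSE] < 0) > 0
  subset_efms(efms, produces & consumes)
}

#' Remove modes that use any of the given reactions
#'
#' Models complete (all-or-none) inactivation of a reaction set: the EFMs of
#' the network without those reactions are exactly the EFMs of the full
#' network whose support is disjoint from the removed set.
#'
#' @param efms An `efm_set`.
#' @param removed Character vector of reaction ids.
#' @return The filtered `efm_set`.
#' @export
knockout_filter <- function(efms, removed) {
  removed <- intersect(as.character(removed), rownames(efms$modes))
  if (length(removed) == 0L) return(efms)
  keep <- colSums(abs(efms$modes[removed, , drop = FALSE])) == 0
  subset_efms(efms, keep)
}

#' Which modes are affected by a regulated reaction set?
#'
#' A mode is affected if its support intersects the regulated set, i.e. it
#' uses at least one reaction whose enzyme is under circadian control.
#'
#' @param efms An `efm_set`, a `flux_mode`, or a named flux vector.
#' @param regulated Character vector of regulated reaction ids (or a
#'   `regulation_annotation`).
#' @return Logical vector (one element per mode).
#' @export
is_affected <- function(efms, regulated) {
  if (inherits(regulated, "regulation_annotation"))
    regulated <- regulated$regulated_reactions
  regulated <- as.character(regulated)
  if (inherits(efms, "flux_mode")) efms <- efms$fluxes
  if (is.numeric(efms)) {
    return(length(intersect(names(efms)[efms != 0], regulated)) > 0)
  }
  regulated <- intersect(regulated, rownames(efms$modes))
  if (length(regulated) == 0L) return(rep(FALSE, ncol(efms$modes)))
  colSums(abs(efms$modes[regulated, , drop = FALSE])) > 0
}

#' Order-independent canonical keys of an EFM set
#'
#' One string per mode, built from sorted (reaction id, flux) pairs; two
#' enumerations of the same network (e.g. with permuted reaction order)
#' yield equal key sets.
#'
#' @param efms An `efm_set` or a flux matrix with reaction-id rownames.
#' @return Character vector of keys.
#' @export
efm_keys <- function(efms) {
  V <- if (inherits(efms, "efm_set")) efms$modes else efms
  rid <- rownames(V)
  vapply(seq_len(ncol(V)), function(k) {
    v <- V[, k]
    nz <- which(v != 0)
    nz <- nz[order(rid[nz])]
    paste(paste0(rid[nz], "=", v[nz]), collapse = ";")
  }, character(1))
}

network_hash <- function(net) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(net$name,
               apply(net$metabolites, 1, paste, collapse = "\t"),
               vapply(net$reactions, format_equation, character(1))), tf)
  unname(tools::md5sum(tf))
}

#' Write / read an EFM set as wide TSV
#'
#' One row per mode, one column per reaction, integer fluxes; a `#`-prefixed
#' header records the network hash and enumeration options so runs can be
#' matched to models.
#'
#' @param efms An `efm_set`.
#' @param path Output file.
#' @return `write_efms` returns `path` invisibly; `read_efms` returns the
#'   flux matrix (reactions x modes) with the header metadata as attributes.
#' @export
write_efms <- function(efms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# network_hash=", network_hash(efms$network)),
    paste0("# n_modes=", ncol(efms$modes), " cap=", efms$meta$cap,
           " algorithm=", efms$meta$algorithm)), con)
  tab <- as.data.frame(t(efms$modes))
  tab <- cbind(mode = rownames(tab), tab)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_efms
#' @export
read_efms <- function(path) {
  header <- character()
  lines <- readLines(path, n = 10L)
  header <- lines[startsWith(lines, "#")]
  tab <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  V <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(V) <- tab$mode
  attr(V, "header") <- header
  V
}
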