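#' Carbon yield of a flux mode
#'
#' The yield Y of a mode for a target amino acid is the number of carbon
#' atoms delivered into the target per carbon atom consumed from the
#' designated carbon sources, computed from the overall chemical equation of
#' the mode:
#' Y = (net target production x target carbon count) /
#'     sum over net-consumed carbon sources of (consumption x carbon count).
#' CO2 is never a designated source, so Y < 1 corresponds to net CO2 release
#' and Y > 1 to non-photosynthetic CO2 incorporation.
#'
#' @param mode A `flux_mode`, a named flux vector, or a precomputed overall
#'   equation (named vector over external metabolites, attribute-free).
#' @param target External metabolite id.
#' @param carbon_sources Character vector of designated source ids.
#' @param net The [metabolic_network()].
#' @return A single non-negative number.
#' @export
carbon_yield <- function(mode, target, carbon_sources, net) {
  if (inherits(mode, "flux_mode")) ov <- mode$overall
  else if (!is.null(names(mode)) && all(names(mode) %in% names(net$reactions)))
    ov <- overall_equation(mode, net)
  else ov <- mode
  carbon <- setNames(net$metabolites$carbon_count, net$metabolites$id)
  if ("CO2" %in% toupper(carbon_sources))
    stop("CO2 must not be a designated carbon source")
  prod <- if (target %in% names(ov)) ov[[target]] else 0
  if (prod <= 0) stop("mode does not net-produce target '", target, "'")
  src <- intersect(carbon_sources, names(ov))
  cons <- -ov[src]
  cons <- cons[cons > 0]
  den <- sum(cons * carbon[names(cons)])
  if (den <= 0)
    stop("mode consumes no designated carbon source; yield undefined")
  prod * carbon[[target]] / den
}

#' Carbon yields of every mode in a set
#'
#' @param efms An `efm_set`, typically already filtered by
#'   [classify_by_target()].
#' @param target External metabolite id.
#' @param carbon_sources Source ids; defaults to the network configuration.
#' @param regulated Optional regulated reaction ids (or a
#'   `regulation_annotation`) used to fill the `affected` column.
#' @return Data frame of yield records: `mode`, `target`, `yield`,
#'   `affected`.
#' @export
carbon_yields <- function(efms, target, carbon_sources = NULL,
                          regulated = character()) {
  net <- efms$network
  carbon_sources <- carbon_sources %||% net$config$carbon_sources
  carbon <- setNames(net$metabolites$carbon_count, net$metabolites$id)
  OV <- overall_matrix(efms)
  src <- intersect(carbon_sources, rownames(OV))
  prod <- OV[target, ]
  consM <- pmax(-OV[src, , drop = FALSE], 0)
  den <- drop(carbon[src] %*% consM)
  if (any(prod <= 0) || any(den <= 0))
    stop("every mode must net-produce the target and consume a carbon source; ",
         "run classify_by_target() first")
  data.frame(
    mode = colnames(efms$modes) %||% seq_len(ncol(efms$modes)),
    target = target,
    yield = prod * carbon[[target]] / den,
    affected = as.logical(is_affected(efms, regulated)),
    stringsAsFactors = FALSE)
}

#' Quantiles of a weighted empirical distribution
#'
#' Linear-interpolation quantiles on the weighted empirical CDF. For integer
#' weight ratios this is exactly the usual (type 7) quantile of the sample
#' with each value replicated in proportion to its weight, which is the
#' boxplot convention used when affected modes are down-weighted to 1/10.
#'
#' @param x Numeric values.
#' @param w Positive weights (recycled).
#' @param probs Probabilities.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = 1, probs = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(length(x) > 0, all(w > 0))
  w <- rep_len(w, length(x))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  W <- cw[length(cw)]
  at <- function(j) x[which(cw >= j - 1e-12)[1]]  # j-th replicated order statistic
  vapply(probs, function(p) {
    h <- (W - 1) * p + 1
    lo <- floor(h)
    v1 <- at(max(lo, 1))
    v2 <- at(min(lo + 1, W))
    v1 + (h - lo) * (v2 - v1)
  }, numeric(1))
}

#' Summarise a yield distribution under a downregulation scheme
#'
#' Three schemes mirror the three modelling stances on circadian control:
#' `"all"` (no regulation: plain statistics over every mode), `"knockout"`
#' (complete night-time inactivation: statistics over the unaffected modes
#' only; an empty result is reported as infeasible, the arginine case), and
#' `"weighted"` (partial downregulation: affected modes keep weight
#' `w_affected`, default 1/10, unaffected weight 1; quantiles come from the
#' weighted empirical CDF and the weighted mean is
#' sum(w_i y_i) / sum(w_i)). With `w_affected = 1` the weighted mean reduces
#' to the plain mean.
#'
#' @param records Data frame of yield records as from [carbon_yields()]
#'   (columns `yield` and `affected`).
#' @param scheme One of `"all"`, `"knockout"`, `"weighted"`.
#' @param w_affected Weight in (0, 1] applied to affected modes.
#' @return One-row data frame: `scheme`, `n_modes`, `n_affected`, `min`,
#'   `q1`, `median`, `q3`, `max`, `mean`, `weighted_mean`, `feasible`.
#' @export
summarise_yields <- function(records, scheme = c("all", "knockout", "weighted"),
                             w_affected = 0.1) {
  scheme <- match.arg(scheme)
  if (scheme == "weighted" && (w_affected <= 0 || w_affected > 1))
    stop("w_affected must lie in (0, 1]")
  infeasible <- function() data.frame(
    scheme = scheme, n_modes = 0L, n_affected = 0L, min = NA_real_,
    q1 = NA_real_, median = NA_real_, q3 = NA_real_, max = NA_real_,
    mean = NA_real_, weighted_mean = NA_real_, feasible = FALSE)
  if (nrow(records) == 0L) return(infeasible())
  y <- records$yield
  aff <- records$affected
  if (scheme == "knockout") {
    y_used <- y[!aff]
    if (length(y_used) == 0L) return(infeasible())
    w <- rep(1, length(y_used))
  } else if (scheme == "weighted") {
    y_used <- y
    w <- ifelse(aff, w_affected, 1)
  } else {
    y_used <- y
    w <- rep(1, length(y_used))
  }
  # scale weights to replication counts (affected 1, unaffected 1/w) so the
  # weighted quantiles equal those of the explicitly replicated sample
  q <- weighted_quantile(y_used, w / min(w))
  data.frame(
    scheme = scheme, n_modes = length(y), n_affected = sum(aff),
    min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    mean = mean(y_used), weighted_mean = sum(w * y_used) / sum(w),
    feasible = TRUE)
}

#' Compare yield distributions across targets and schemes
#'
#' Runs [classify_by_target()], [carbon_yields()] and [summarise_yields()]
#' for each target and scheme and flags the headline pattern: a target whose
#' mean (or weighted mean) yield increases under downregulation while its
#' maximum yield does not increase, i.e. the regulator predominantly
#' suppresses low-yield routes.
#'
#' @param efms An `efm_set` for the full network.
#' @param regulation Regulated reaction ids or a `regulation_annotation`.
#' @param targets Character vector of target metabolite ids; defaults to the
#'   network configuration.
#' @param schemes Subset of `c("all", "knockout", "weighted")`.
#' @param carbon_sources Source ids; defaults to the network configuration.
#' @param w_affected Weight for the weighted scheme.
#' @return Data frame with one row per (target, scheme), the summary columns
#'   of [summarise_yields()], and logical columns `mean_increases` and
#'   `max_not_increased` (relative to that target's `"all"` row; `NA` for
#'   the `"all"` rows themselves).
#' @export
scenario_compare <- function(efms, regulation, targets = NULL,
                             schemes = c("all", "knockout", "weighted"),
                             carbon_sources = NULL, w_affected = 0.1) {
  net <- efms$network
  targets <- targets %||% net$config$targets
  carbon_sources <- carbon_sources %||% net$config$carbon_sources
  if (inherits(regulation, "regulation_annotation"))
    regulation <- regulation$regulated_reactions
  rows <- list()
  for (tg in targets) {
    sel <- classify_by_target(efms, tg, carbon_sources)
    recs <- if (n_modes(sel) > 0)
      carbon_yields(sel, tg, carbon_sources, regulation)
    else data.frame(mode = character(), target = character(),
                    yield = numeric(), affected = logical())
    base <- summarise_yields(recs, "all")
    for (sc in schemes) {
      s <- if (sc == "all") base else summarise_yields(recs, sc, w_affected)
      cmp_mean <- if (sc == "weighted") s$weighted_mean else s$mean
      s$mean_increases <- if (sc == "all") NA else
        isTRUE(s$feasible) && isTRUE(base$feasible) && cmp_mean > base$mean
      s$max_not_increased <- if (sc == "all") NA else
        isTRUE(s$feasible) && isTRUE(base$feasible) && s$max <= base$max + 1e-12
      rows[[length(rows) + 1L]] <- cbind(data.frame(target = tg), s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
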