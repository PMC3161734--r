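#' Construct a reaction
#'
#' A reaction is a signed stoichiometry map over metabolite ids (negative
#' coefficients are substrates, positive are products) together with a
#' reversibility flag and optional enzyme annotation.
#'
#' @param id Reaction identifier (short token, unique within a network).
#' @param stoich Named numeric vector of signed stoichiometric coefficients.
#'   Zero coefficients are dropped.
#' @param reversible Logical; `TRUE` if the reaction may carry negative flux.
#' @param enzyme Free-text enzyme name.
#' @param genes Character vector of gene identifiers encoding the enzyme.
#' @param ec Optional EC number.
#' @return An object of class `cf_reaction`.
#' @export
reaction <- function(id, stoich, reversible = FALSE, enzyme = "",
                     genes = character(), ec = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("stoichiometry must be a named numeric vector")
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L)
    stop("reaction '", id, "': stoichiometry is empty after dropping zeros")
  if (anyDuplicated(names(stoich)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  structure(
    list(id = id, stoich = stoich, reversible = isTRUE(reversible),
         enzyme = enzyme, genes = as.character(genes), ec = ec),
    class = "cf_reaction")
}

#' Construct a metabolic network
#'
#' @param metabolites Data frame with columns `id`, `name`, `carbon_count`,
#'   `is_external`, and optionally `skip_carbon_check` (metabolites whose
#'   carbon is part of a conserved carrier moiety, e.g. the adenine ring of
#'   ATP, and is excluded from carbon balancing).
#' @param reactions List of [reaction()] objects.
#' @param name Network name.
#' @param config Optional model configuration list with elements
#'   `carbon_sources`, `targets` and `regulated_reactions` (see
#'   [read_model_config()]).
#' @return An object of class `metabolic_network` with fields `metabolites`
#'   (data frame in declaration order), `reactions` (named list) and `config`.
#' @export
metabolic_network <- function(metabolites, reactions, name = "network",
                              config = list()) {
  stopifnot(is.data.frame(metabolites))
  needed <- c("id", "carbon_count", "is_external")
  if (!all(needed %in% names(metabolites)))
    stop("metabolite table must have columns: ", paste(needed, collapse = ", "))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$skip_carbon_check))
    metabolites$skip_carbon_check <- FALSE
  metabolites$id <- as.character(metabolites$id)
  metabolites$carbon_count <- as.numeric(metabolites$carbon_count)
  metabolites$is_external <- as.logical(metabolites$is_external)
  metabolites$skip_carbon_check <- as.logical(metabolites$skip_carbon_check)
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (any(is.na(metabolites$carbon_count)) || any(metabolites$carbon_count < 0))
    stop("carbon_count must be a non-negative number for every metabolite")

  if (inherits(reactions, "cf_reaction")) reactions <- list(reactions)
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate reaction id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(reactions) <- ids
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), metabolites$id)
    if (length(unknown))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  net <- structure(
    list(name = name, metabolites = metabolites, reactions = reactions,
         config = config),
    class = "metabolic_network")
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_int <- sum(!x$metabolites$is_external)
  cat(sprintf("<metabolic_network> %s: %d reactions, %d metabolites (%d internal, %d external)\n",
              x$name, length(x$reactions), nrow(x$metabolites), n_int,
              nrow(x$metabolites) - n_int))
  if (length(x$config$regulated_reactions))
    cat("  regulated reactions:", paste(x$config$regulated_reactions, collapse = ", "), "\n")
  invisible(x)
}

#' Reaction and metabolite ids of a network
#' @param net A [metabolic_network()].
#' @return Character vector of identifiers in declaration order.
#' @export
reaction_ids <- function(net) names(net$reactions)

#' @rdname reaction_ids
#' @export
metabolite_ids <- function(net) net$metabolites$id

#' Stoichiometric matrix
#'
#' Rows are metabolites in declaration order, columns are reactions in
#' declaration order. With `internal_only = TRUE` (the default) only rows of
#' internal metabolites are kept; these are the rows entering the steady-state
#' constraint S v = 0.
#'
#' @param net A [metabolic_network()].
#' @param internal_only Drop rows of external (buffered) metabolites.
#' @return Numeric matrix with dimnames.
#' @export
stoich_matrix <- function(net, internal_only = TRUE) {
  mets <- net$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = length(net$reactions),
              dimnames = list(mets, names(net$reactions)))
  for (r in net$reactions) S[names(r$stoich), r$id] <- r$stoich
  if (internal_only) S <- S[!net$metabolites$is_external, , drop = FALSE]
  S
}

parse_coefficient <- function(tok) {
  if (grepl("^[0-9]+/[0-9]+$", tok)) {
    pq <- as.numeric(strsplit(tok, "/", fixed = TRUE)[[1]])
    if (pq[2] == 0) return(NA_real_)
    return(pq[1] / pq[2])
  }
  suppressWarnings(as.numeric(tok))
}

#' Parse a reaction equation string
#'
#' Equations use coefficient-space-metabolite terms joined by `" + "`, with
#' sides joined by `" -> "` (irreversible) or `" <-> "` (reversible), e.g.
#' `"1 G6P + 1 ATP -> 1 F16BP + 1 ADP"`. Coefficients may be integers,
#' decimals or fractions (`"1/2"`); a bare metabolite token means
#' coefficient 1.
#'
#' @param eq Equation string.
#' @return List with `stoich` (named signed numeric) and `reversible`.
#' @export
parse_equation <- function(eq) {
  stopifnot(is.character(eq), length(eq) == 1L)
  reversible <- grepl("<->", eq, fixed = TRUE)
  if (!grepl("->", eq, fixed = TRUE))
    stop("malformed equation (no direction token): '", eq, "'")
  sides <- if (reversible) strsplit(eq, "<->", fixed = TRUE)[[1]]
           else strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("malformed equation (expected exactly one direction token): '", eq, "'")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) stop("malformed equation (empty side): '", eq, "'")
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      if (!nzchar(term)) stop("malformed equation (empty term): '", eq, "'")
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) { coef <- 1; met <- toks[1] }
      else if (length(toks) == 2L) {
        coef <- parse_coefficient(toks[1]); met <- toks[2]
        if (is.na(coef)) stop("malformed coefficient '", toks[1], "' in equation: '", eq, "'")
      } else stop("malformed term '", term, "' in equation: '", eq, "'")
      if (grepl("^[0-9./]+$", met))
        stop("malformed term '", term, "' in equation: '", eq, "'")
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- c(lhs, numeric(0))
  for (m in names(rhs)) stoich[m] <- (if (m %in% names(stoich)) stoich[[m]] else 0) + rhs[[m]]
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L) stop("equation cancels to nothing: '", eq, "'")
  list(stoich = stoich, reversible = reversible)
}

format_coefficient <- function(x) {
  if (abs(x - round(x)) < 1e-12) return(format(round(x), scientific = FALSE))
  for (q in 2:1024) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(paste0(round(p), "/", q))
  }
  format(x)
}

format_equation <- function(r) {
  fmt_side <- function(coefs) {
    paste(vapply(seq_along(coefs), function(i)
      paste(format_coefficient(abs(coefs[[i]])), names(coefs)[i]), character(1)),
      collapse = " + ")
  }
  lhs <- r$stoich[r$stoich < 0]
  rhs <- r$stoich[r$stoich > 0]
  arrow <- if (r$reversible) "<->" else "->"
  paste(fmt_side(lhs), arrow, fmt_side(rhs))
}

#' Read a model configuration file
#'
#' The configuration lists the model-level choices that are not chemistry:
#' which metabolites are external (buffered), which reactions are under
#' circadian (CHLAMY1) control, which externals are the designated carbon
#' sources, and which are the biosynthetic targets. YAML and JSON are
#' accepted (chosen by file extension).
#'
#' @param path File path.
#' @return List with elements `external`, `regulated_reactions`,
#'   `carbon_sources`, `targets` (each a character vector, possibly empty).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (f in c("external", "regulated_reactions", "carbon_sources", "targets"))
    cfg[[f]] <- as.character(cfg[[f]] %||% character())
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a reaction-table model
#'
#' Reads the two-table TSV dialect: a reaction table with columns
#' `reaction_id`, `equation`, `enzyme`, `ec`, `genes` (comma-separated), and a
#' metabolite table with columns `metabolite_id`, `name`, `carbon_count`,
#' `skip_carbon_check`. External metabolites are declared in the model
#' configuration, not in the tables, because buffering is a property of the
#' model variant rather than of the chemistry.
#'
#' @param reactions_path Path to the reaction table TSV.
#' @param metabolites_path Path to the metabolite table TSV.
#' @param config Model configuration: a list (see [read_model_config()]) or a
#'   path to a YAML/JSON file.
#' @param name Network name; defaults to the reaction-table file name.
#' @return A validated [metabolic_network()].
#' @export
parse_reaction_table <- function(reactions_path, metabolites_path, config,
                                 name = NULL) {
  for (p in c(reactions_path, metabolites_path))
    if (!file.exists(p)) stop("file not found: ", p)
  if (is.character(config)) config <- read_model_config(config)
  mtab <- read.delim(metabolites_path, sep = "\t", stringsAsFactors = FALSE,
                     comment.char = "#", check.names = FALSE)
  if (!all(c("metabolite_id", "carbon_count") %in% names(mtab)))
    stop("metabolite table must have columns metabolite_id, carbon_count")
  mets <- data.frame(
    id = as.character(mtab$metabolite_id),
    name = as.character(mtab$name %||% mtab$metabolite_id),
    carbon_count = as.numeric(mtab$carbon_count),
    is_external = as.character(mtab$metabolite_id) %in% (config$external %||% character()),
    skip_carbon_check = as.logical(mtab$skip_carbon_check %||% FALSE),
    stringsAsFactors = FALSE)
  rtab <- read.delim(reactions_path, sep = "\t", stringsAsFactors = FALSE,
                     comment.char = "#", check.names = FALSE)
  if (!all(c("reaction_id", "equation") %in% names(rtab)))
    stop("reaction table must have columns reaction_id, equation")
  if (anyDuplicated(rtab$reaction_id))
    stop("duplicate reaction id in ", reactions_path, ": ",
         paste(unique(rtab$reaction_id[duplicated(rtab$reaction_id)]), collapse = ", "))
  reactions <- vector("list", nrow(rtab))
  for (i in seq_len(nrow(rtab))) {
    parsed <- tryCatch(parse_equation(rtab$equation[i]), error = function(e)
      stop("line ", i, " of ", basename(reactions_path), ": ", conditionMessage(e),
           call. = FALSE))
    unknown <- setdiff(names(parsed$stoich), mets$id)
    if (length(unknown))
      stop("line ", i, " of ", basename(reactions_path),
           ": unknown metabolite id(s): ", paste(unknown, collapse = ", "))
    genes <- as.character(rtab$genes %||% rep("", nrow(rtab)))
    genes[is.na(genes)] <- ""
    genes_i <- trimws(strsplit(genes[i], ",")[[1]])
    reactions[[i]] <- reaction(
      id = as.character(rtab$reaction_id[i]), stoich = parsed$stoich,
      reversible = parsed$reversible,
      enzyme = as.character((rtab$enzyme %||% rep("", nrow(rtab)))[i]),
      genes = genes_i[nzchar(genes_i)],
      ec = as.character((rtab$ec %||% rep(NA, nrow(rtab)))[i]))
  }
  metabolic_network(mets, reactions,
                    name = name %||% tools::file_path_sans_ext(basename(reactions_path)),
                    config = config)
}

#' Write a network back to the reaction-table dialect
#'
#' Inverse of [parse_reaction_table()]; a parse/write/parse round trip yields
#' an equivalent network (same stoichiometric matrix, reversibility and
#' external set).
#'
#' @param net A [metabolic_network()].
#' @param reactions_path,metabolites_path Output TSV paths.
#' @return Invisibly, `net`.
#' @export
write_reaction_table <- function(net, reactions_path, metabolites_path) {
  rtab <- data.frame(
    reaction_id = names(net$reactions),
    equation = vapply(net$reactions, format_equation, character(1)),
    enzyme = vapply(net$reactions, function(r) r$enzyme %||% "", character(1)),
    ec = vapply(net$reactions, function(r) r$ec %||% NA_character_, character(1)),
    genes = vapply(net$reactions, function(r) paste(r$genes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(rtab, reactions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  mtab <- data.frame(
    metabolite_id = net$metabolites$id, name = net$metabolites$name,
    carbon_count = net$metabolites$carbon_count,
    skip_carbon_check = net$metabolites$skip_carbon_check,
    stringsAsFactors = FALSE)
  write.table(mtab, metabolites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}

#' Check carbon balance of every reaction
#'
#' For each reaction the substrate-side and product-side carbon totals are
#' compared, skipping metabolites flagged `skip_carbon_check` (conserved
#' carrier moieties such as the adenine ring of ATP/ADP, which are never net
#' consumed and whose carbon is not part of the metabolic skeleton being
#' balanced).
#'
#' @param net A [metabolic_network()].
#' @return Data frame with one row per unbalanced reaction (columns
#'   `reaction_id`, `substrate_carbon`, `product_carbon`, `difference`);
#'   zero rows means the network is carbon balanced.
#' @export
validate_carbon_balance <- function(net) {
  carbon <- setNames(net$metabolites$carbon_count, net$metabolites$id)
  skip <- setNames(net$metabolites$skip_carbon_check, net$metabolites$id)
  rows <- lapply(net$reactions, function(r) {
    s <- r$stoich[!skip[names(r$stoich)]]
    lhs <- sum(abs(s[s < 0]) * carbon[names(s)[s < 0]])
    rhs <- sum(s[s > 0] * carbon[names(s)[s > 0]])
    if (abs(lhs - rhs) > 1e-9)
      data.frame(reaction_id = r$id, substrate_carbon = lhs,
                 product_carbon = rhs, difference = rhs - lhs,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(reaction_id = character(), substrate_carbon = numeric(),
                      product_carbon = numeric(), difference = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract a subnetwork
#'
#' Removes the given reactions, prunes metabolites that are no longer
#' referenced, and optionally replaces the external-metabolite set (used for
#' model variants that change the carbon source, e.g. feeding
#' glyceraldehyde-3-phosphate instead of G6P after removing glycolysis and
#' the pentose phosphate pathway). Stoichiometric coefficients of surviving
#' reactions are never altered.
#'
#' @param net A [metabolic_network()].
#' @param drop_reactions Character vector of reaction ids to remove.
#' @param externals_override Optional character vector replacing the external
#'   metabolite set of the result.
#' @return A new [metabolic_network()].
#' @export
subnetwork <- function(net, drop_reactions, externals_override = NULL) {
  drop_reactions <- as.character(drop_reactions)
  unknown <- setdiff(drop_reactions, names(net$reactions))
  if (length(unknown))
    stop("unknown reaction id(s) in drop set: ", paste(unknown, collapse = ", "))
  keep <- setdiff(names(net$reactions), drop_reactions)
  if (length(keep) == 0L) stop("subnetwork would drop every reaction")
  reactions <- net$reactions[keep]
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  mets <- net$metabolites[net$metabolites$id %in% used, , drop = FALSE]
  rownames(mets) <- NULL
  if (!is.null(externals_override)) {
    unknown <- setdiff(externals_override, mets$id)
    if (length(unknown))
      stop("externals_override names unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    mets$is_external <- mets$id %in% externals_override
  }
  cfg <- net$config
  cfg$external <- mets$id[mets$is_external]
  cfg$regulated_reactions <- intersect(cfg$regulated_reactions %||% character(), keep)
  cfg$carbon_sources <- intersect(cfg$carbon_sources %||% character(), mets$id)
  cfg$targets <- intersect(cfg$targets %||% character(), mets$id)
  metabolic_network(mets, reactions, name = paste0(net$name, "_sub"), config = cfg)
}
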