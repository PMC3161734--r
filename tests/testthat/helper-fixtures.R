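# Shared builders for small in-code fixtures.

# Build a network from equation strings; all metabolites get the same carbon
# count unless overridden.
net_from_equations <- function(eqs, externals, carbons = NULL, config = list()) {
  parsed <- lapply(eqs, parse_equation)
  mets <- unique(unlist(lapply(parsed, function(p) names(p$stoich))))
  carbon <- setNames(rep(3, length(mets)), mets)
  if (!is.null(carbons)) carbon[names(carbons)] <- carbons
  mtab <- data.frame(id = mets, name = mets, carbon_count = carbon[mets],
                     is_external = mets %in% externals,
                     skip_carbon_check = FALSE, stringsAsFactors = FALSE)
  rxns <- lapply(seq_along(eqs), function(i)
    reaction(names(eqs)[i], parsed[[i]]$stoich, parsed[[i]]$reversible))
  config$external <- externals
  metabolic_network(mtab, rxns, "test_net", config = config)
}

# Reorder the reactions of a network (used to check order invariance).
permute_reactions <- function(net, perm) {
  metabolic_network(net$metabolites, net$reactions[perm], net$name,
                    config = net$config)
}

# Write a two-table model + config to a temp dir; returns the three paths.
write_model_files <- function(net, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  rp <- file.path(dir, "reactions.tsv")
  mp <- file.path(dir, "metabolites.tsv")
  cp <- file.path(dir, "config.yaml")
  write_reaction_table(net, rp, mp)
  yaml::write_yaml(list(
    external = as.list(net$metabolites$id[net$metabolites$is_external]),
    regulated_reactions = as.list(net$config$regulated_reactions %||% character()),
    carbon_sources = as.list(net$config$carbon_sources %||% character()),
    targets = as.list(net$config$targets %||% character())), cp)
  list(reactions = rp, metabolites = mp, config = cp)
}

`%||%` <- circaflux:::`%||%`

# Pairwise support-minimality check: no mode's support strictly contained in
# another's.
supports_minimal <- function(efms) {
  A <- t(efms$modes != 0) * 1        # modes x reactions
  if (nrow(A) < 2) return(TRUE)
  # M[i, j] = number of reactions used by i but not by j; a strict subset
  # (M[i, j] == 0 with the reverse positive) violates minimality.  Equal
  # supports are allowed: they are opposite orientations of a fully
  # reversible mode.
  M <- A %*% t(1 - A)
  !any(M == 0 & t(M) > 0)
}

expect_same_modes <- function(a, b) {
  expect_setequal(efm_keys(a), efm_keys(b))
}
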