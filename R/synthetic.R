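#' Specification for the synthetic-data generators
#'
#' One integer seed drives a separate pseudo-random stream per generator
#' (network / UTR / proteome), so each fixture is reproducible independently
#' of call order. Unspecified parameters take the defaults below.
#'
#' @param seed Integer seed.
#' @param network Overrides for the network generator: `n_pathways`,
#'   `pathway_length` (reactions per source-to-sink chain), `n_branch_points`
#'   (carbon-conserving split reactions), `reversibility_fraction`,
#'   `carbon_range` (inclusive bounds for per-pathway carbon counts),
#'   `share_prob` (chance a chain reuses an existing intermediate),
#'   `max_reactions`.
#' @param utr Overrides for the UTR generator: `n_sequences`, `length`,
#'   `motif_rate` (probability a sequence carries one planted repeat),
#'   `repeat_counts` (pool of planted (UG)k unit counts), `min_repeats`
#'   (background runs are kept below this threshold).
#' @param proteome Overrides for the proteome generator: `n_sequences`,
#'   `mean_length`, `residue_freq` (named frequency vector over the 20
#'   standard residues, summing to 1).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, network = list(), utr = list(),
                           proteome = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  spec <- list(
    seed = as.integer(seed),
    network = modifyList(list(
      n_pathways = 2L, pathway_length = 4L, n_branch_points = 1L,
      reversibility_fraction = 0.25, carbon_range = c(2L, 6L),
      share_prob = 0.3, max_reactions = 12L), network),
    utr = modifyList(list(
      n_sequences = 10L, length = 200L, motif_rate = 1,
      repeat_counts = 7:9, min_repeats = 7L), utr),
    proteome = modifyList(list(
      n_sequences = 50L, mean_length = 200L,
      residue_freq = setNames(rep(1 / 20, 20), aa)), proteome))
  if (any(spec$utr$motif_rate < 0 | spec$utr$motif_rate > 1))
    stop("motif_rate must lie in [0, 1]")
  if (abs(sum(spec$proteome$residue_freq) - 1) > 1e-6)
    stop("residue_freq must sum to 1")
  if (any(spec$proteome$residue_freq < 0))
    stop("residue_freq must be non-negative")
  class(spec) <- "synthetic_spec"
  spec
}

with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Toy networks with analytically known elementary flux modes
#'
#' Four hand-built fixtures: `T1_linear` (a three-reaction chain, one mode),
#' `T2_diamond` (two parallel branches, two modes), `T3_revcycle` (two
#' parallel routes of which one is reversible, three modes -- the third is
#' the internal futile cycle through the reversible edge, which is a genuine
#' two-reaction cycle, not a split-pair artefact), and `T4_co2` (a
#' CO2-releasing motif whose single mode has carbon yield exactly 2/3).
#'
#' @param name One of `"T1_linear"`, `"T2_diamond"`, `"T3_revcycle"`,
#'   `"T4_co2"`.
#' @return List with `network` (a [metabolic_network()] whose config carries
#'   `carbon_sources` and `targets`) and `efms_expected` (flux matrix,
#'   reactions x modes).
#' @export
toy_network <- function(name = c("T1_linear", "T2_diamond", "T3_revcycle",
                                 "T4_co2")) {
  name <- match.arg(name)
  mk <- function(ids, carbon, ext) data.frame(
    id = ids, name = ids, carbon_count = carbon,
    is_external = ids %in% ext, skip_carbon_check = FALSE,
    stringsAsFactors = FALSE)
  if (name == "T1_linear") {
    mets <- mk(c("Aext", "A", "B", "Bext"), rep(3, 4), c("Aext", "Bext"))
    rxns <- list(
      reaction("R1", c(Aext = -1, A = 1)),
      reaction("R2", c(A = -1, B = 1)),
      reaction("R3", c(B = -1, Bext = 1)))
    net <- metabolic_network(mets, rxns, "T1_linear",
      config = list(external = c("Aext", "Bext"), carbon_sources = "Aext",
                    targets = "Bext", regulated_reactions = character()))
    exp <- matrix(c(1, 1, 1), 3, 1, dimnames = list(c("R1", "R2", "R3"), NULL))
  } else if (name == "T2_diamond") {
    mets <- mk(c("Sext", "A", "B", "C", "P", "Pext"), rep(3, 6), c("Sext", "Pext"))
    rxns <- list(
      reaction("R1", c(Sext = -1, A = 1)),
      reaction("R2", c(A = -1, B = 1)),
      reaction("R3", c(A = -1, C = 1)),
      reaction("R4", c(B = -1, P = 1)),
      reaction("R5", c(C = -1, P = 1)),
      reaction("R6", c(P = -1, Pext = 1)))
    net <- metabolic_network(mets, rxns, "T2_diamond",
      config = list(external = c("Sext", "Pext"), carbon_sources = "Sext",
                    targets = "Pext", regulated_reactions = character()))
    exp <- cbind(c(1, 1, 0, 1, 0, 1), c(1, 0, 1, 0, 1, 1))
    rownames(exp) <- paste0("R", 1:6)
  } else if (name == "T3_revcycle") {
    mets <- mk(c("Sext", "A", "B", "Bext"), rep(3, 4), c("Sext", "Bext"))
    rxns <- list(
      reaction("R1", c(Sext = -1, A = 1)),
      reaction("R2", c(A = -1, B = 1), reversible = TRUE),
      reaction("R3", c(A = -1, B = 1)),
      reaction("R4", c(B = -1, Bext = 1)))
    net <- metabolic_network(mets, rxns, "T3_revcycle",
      config = list(external = c("Sext", "Bext"), carbon_sources = "Sext",
                    targets = "Bext", regulated_reactions = character()))
    exp <- cbind(c(1, 1, 0, 1), c(1, 0, 1, 1), c(0, -1, 1, 0))
    rownames(exp) <- paste0("R", 1:4)
  } else {
    mets <- data.frame(
      id = c("Sext", "S", "T", "C", "Text", "CO2"),
      name = c("Sext", "S", "T", "C", "Text", "CO2"),
      carbon_count = c(3, 3, 2, 1, 2, 1),
      is_external = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
      skip_carbon_check = FALSE, stringsAsFactors = FALSE)
    rxns <- list(
      reaction("R1", c(Sext = -1, S = 1)),
      reaction("R2", c(S = -1, T = 1, C = 1)),
      reaction("R3", c(T = -1, Text = 1)),
      reaction("R4", c(C = -1, CO2 = 1)))
    net <- metabolic_network(mets, rxns, "T4_co2",
      config = list(external = c("Sext", "Text", "CO2"),
                    carbon_sources = "Sext", targets = "Text",
                    regulated_reactions = character()))
    exp <- matrix(1, 4, 1, dimnames = list(paste0("R", 1:4), NULL))
  }
  list(network = net, efms_expected = exp)
}

#' Generate a random carbon-balanced network
#'
#' Composes random source-to-sink linear pathways that may share internal
#' intermediates of equal carbon count, plus optional carbon-conserving
#' split reactions (branch points), so [validate_carbon_balance()] holds by
#' construction, every internal metabolite lies on a source-to-sink path,
#' and at least one elementary mode exists. Deterministic under the spec
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [metabolic_network()].
#' @export
random_network <- function(spec) {
  p <- spec$network
  if (p$n_pathways < 1) stop("n_pathways must be at least 1")
  if (p$pathway_length < 2) stop("pathway_length must be at least 2")
  with_stream(spec$seed, 1000L, {
    mets <- data.frame(id = character(), name = character(),
                       carbon_count = numeric(), is_external = logical(),
                       skip_carbon_check = logical(), stringsAsFactors = FALSE)
    rxns <- list()
    met_counter <- 0L
    add_met <- function(id, carbon, ext) {
      mets <<- rbind(mets, data.frame(
        id = id, name = id, carbon_count = carbon, is_external = ext,
        skip_carbon_check = FALSE, stringsAsFactors = FALSE))
      id
    }
    add_rxn <- function(stoich) {
      id <- paste0("R", length(rxns) + 1L)
      rxns[[id]] <<- reaction(id, stoich,
        reversible = runif(1) < p$reversibility_fraction)
      id
    }
    internal_pool <- function(carbon)
      mets$id[!mets$is_external & mets$carbon_count == carbon]
    pick1 <- function(x) x[sample.int(length(x), 1L)]
    carbons <- integer(0)
    for (pw in seq_len(p$n_pathways)) {
      if (length(rxns) >= p$max_reactions) break
      carbon <- if (length(carbons) && runif(1) < 0.5) pick1(carbons)
                else pick1(seq(p$carbon_range[1], p$carbon_range[2]))
      carbons <- unique(c(carbons, carbon))
      prev <- add_met(paste0("SRC", pw), carbon, TRUE)
      for (step in seq_len(p$pathway_length - 1L)) {
        if (length(rxns) >= p$max_reactions) break
        pool <- setdiff(internal_pool(carbon), prev)
        nxt <- if (length(pool) && runif(1) < p$share_prob) pick1(pool)
               else {
                 met_counter <- met_counter + 1L
                 add_met(paste0("M", met_counter), carbon, FALSE)
               }
        add_rxn(setNames(c(-1, 1), c(prev, nxt)))
        prev <- nxt
      }
      if (length(rxns) < p$max_reactions)
        add_rxn(setNames(c(-1, 1), c(prev, add_met(paste0("SNK", pw), carbon, TRUE))))
    }
    for (b in seq_len(p$n_branch_points)) {
      if (length(rxns) + 3L > p$max_reactions) break
      cands <- mets$id[!mets$is_external & mets$carbon_count >= 2]
      if (!length(cands)) break
      m <- pick1(cands)
      c0 <- mets$carbon_count[mets$id == m]
      c1 <- pick1(seq_len(c0 - 1L))
      met_counter <- met_counter + 1L
      b1 <- add_met(paste0("M", met_counter), c1, FALSE)
      met_counter <- met_counter + 1L
      b2 <- add_met(paste0("M", met_counter), c0 - c1, FALSE)
      add_rxn(setNames(c(-1, 1, 1), c(m, b1, b2)))
      add_rxn(setNames(c(-1, 1), c(b1, add_met(paste0("SNKB", b, "a"), c1, TRUE))))
      add_rxn(setNames(c(-1, 1), c(b2, add_met(paste0("SNKB", b, "b"), c0 - c1, TRUE))))
    }
    cfg <- list(external = mets$id[mets$is_external],
                carbon_sources = grep("^SRC", mets$id, value = TRUE),
                targets = grep("^SNK", mets$id, value = TRUE),
                regulated_reactions = character())
    metabolic_network(mets, rxns, sprintf("random_seed%d", spec$seed),
                      config = cfg)
  })
}

break_background_runs <- function(s, min_repeats) {
  repeat {
    h <- scan_ug_repeats(s, min_repeats)
    if (nrow(h) == 0L) return(s)
    mid <- h$start[1] + 2L * (h$repeat_count[1] %/% 2L)  # 0-based, on a T/G boundary
    substr(s, mid + 1L, mid + 1L) <- "A"
  }
}

#' Generate UTR sequences with planted (UG)k repeats
#'
#' Background sequence is uniform DNA with accidental UG runs broken below
#' the detection threshold; each planted repeat is written at a recorded
#' position and flanked by `A` on both sides so it is maximal by
#' construction. Planted repeat counts below the scanning threshold are
#' allowed (they exercise the threshold semantics and are recorded in the
#' truth table like any other plant).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `sequences` (named character vector) and `truth`
#'   (data frame `sequence_id`, `start`, `end`, `repeat_count`, 0-based
#'   half-open, one row per planted repeat).
#' @export
planted_utrs <- function(spec) {
  p <- spec$utr
  with_stream(spec$seed, 2000L, {
    seqs <- character(p$n_sequences)
    names(seqs) <- sprintf("utr%03d", seq_len(p$n_sequences))
    truth <- list()
    for (i in seq_len(p$n_sequences)) {
      s <- paste(sample(c("A", "C", "G", "T"), p$length, replace = TRUE),
                 collapse = "")
      s <- break_background_runs(s, p$min_repeats)
      if (runif(1) < p$motif_rate) {
        k <- if (length(p$repeat_counts) == 1L) p$repeat_counts
             else sample(p$repeat_counts, 1L)
        motif_len <- 2L * k
        if (motif_len + 2L > p$length)
          stop("planted motif longer than sequence")
        start1 <- sample(seq(2L, p$length - motif_len - 1L), 1L)  # 1-based
        motif <- strrep("TG", k)
        substr(s, start1 - 1L, start1 - 1L) <- "A"
        substr(s, start1, start1 + motif_len - 1L) <- motif
        substr(s, start1 + motif_len, start1 + motif_len) <- "A"
        truth[[length(truth) + 1L]] <- data.frame(
          sequence_id = names(seqs)[i], start = start1 - 1L,
          end = start1 - 1L + motif_len, repeat_count = k,
          stringsAsFactors = FALSE)
      }
      seqs[i] <- s
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(sequence_id = character(), start = integer(),
                             end = integer(), repeat_count = integer())
    list(sequences = seqs, truth = truth)
  })
}

#' Sample a synthetic proteome from a residue frequency vector
#'
#' Residues of every sequence are drawn independently from the given
#' frequency vector; sequence lengths are Poisson around `mean_length`.
#' Deterministic under the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Named character vector of protein sequences.
#' @export
synthetic_proteome <- function(spec) {
  p <- spec$proteome
  with_stream(spec$seed, 3000L, {
    lens <- pmax(1L, stats::rpois(p$n_sequences, p$mean_length))
    seqs <- vapply(lens, function(L)
      paste(sample(names(p$residue_freq), L, replace = TRUE,
                   prob = p$residue_freq), collapse = ""), character(1))
    names(seqs) <- sprintf("prot%04d", seq_len(p$n_sequences))
    seqs
  })
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
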