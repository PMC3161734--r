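#' Scan a nucleotide sequence for perfect (UG)k repeats
#'
#' Finds every maximal run of uninterrupted UG dinucleotide units with at
#' least `min_repeats` units -- the binding motif of the circadian
#' RNA-binding factor CHLAMY1 when it occurs in a 3' UTR. Scanning is
#' case-insensitive, T and U are equivalent, and only the given (sense)
#' strand is scanned since the factor binds mRNA. Runs entered mid-phase
#' (e.g. a leading G) are anchored at the first U of the maximal UG-phased
#' run; a maximal run is reported once (a 9-unit run is one hit of
#' `repeat_count` 9, not three overlapping 7-unit hits).
#'
#' @param seq A single nucleotide string (DNA or RNA alphabet).
#' @param min_repeats Minimum number of UG units (default 7, the
#'   experimentally established CHLAMY1 requirement).
#' @return Data frame with columns `start` (0-based), `length` (nucleotides,
#'   always `2 * repeat_count`) and `repeat_count`; zero rows if no hit.
#' @export
scan_ug_repeats <- function(seq, min_repeats = 7L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.numeric(min_repeats) || min_repeats < 1)
    stop("min_repeats must be a positive integer")
  min_repeats <- as.integer(min_repeats)
  empty <- data.frame(start = integer(), length = integer(),
                      repeat_count = integer())
  if (!nzchar(seq)) return(empty)
  s <- chartr("uU", "tT", toupper(seq))
  pat <- sprintf("(?:TG){%d,}", min_repeats)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, length = as.integer(len),
             repeat_count = as.integer(len %/% 2L))
}

#' Scan a UTR FASTA file for (UG)k repeats
#'
#' @param fasta Path to a (multi-record, possibly line-wrapped) FASTA file,
#'   or a named character vector / `Biostrings::XStringSet` of sequences.
#' @param min_repeats Minimum number of UG units.
#' @return Data frame in BED-like form: `sequence_id`, `start`, `end`
#'   (0-based half-open) and `repeat_count`.
#' @export
scan_utr_fasta <- function(fasta, min_repeats = 7L) {
  seqs <- as_sequence_vector(fasta)
  hits <- lapply(names(seqs), function(id) {
    h <- scan_ug_repeats(seqs[[id]], min_repeats)
    if (nrow(h) == 0L) return(NULL)
    data.frame(sequence_id = id, start = h$start, end = h$start + h$length,
               repeat_count = h$repeat_count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), repeat_count = integer())
  rownames(out) <- NULL
  out
}

as_sequence_vector <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readBStringSet(x)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))  # id = first word of header
    return(seqs)
  }
  if (inherits(x, "XStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    return(seqs)
  }
  if (is.character(x)) {
    if (length(x) == 0L) return(setNames(character(0), character(0)))
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret sequences: give a FASTA path, named character vector, or XStringSet")
}

#' Derive the regulated reaction set from UTR motif scans
#'
#' Applies the "entirely encoded" rule: a reaction is under CHLAMY1 control
#' only if every gene encoding its enzyme carries at least one (UG)k repeat
#' in its 3' UTR. If some but not all isoenzyme genes of a reaction carry the
#' motif, the reaction is exempted (an unregulated isoform can carry the
#' flux, so the reaction is simulated as not clock-controlled); genes are
#' only grouped into the same isoform group when the isoforms use the same
#' cofactors, mirroring how cofactor-specific variants (e.g. NADPH- vs
#' NADH-dependent isocitrate dehydrogenase) are modelled as distinct
#' reactions.
#'
#' @param utr_fasta UTR sequences (path, named character vector or
#'   `XStringSet`); sequence ids must match `gene_map$sequence_id`.
#' @param gene_map Path to, or data frame of, the mapping table with columns
#'   `sequence_id`, `gene_id`, `reaction_id`, `isoform_group`.
#' @param net A [metabolic_network()]; reaction ids are validated against it.
#' @param min_repeats Minimum number of UG units.
#' @return An object of class `regulation_annotation`: list with
#'   `regulated_reactions`, `isoenzyme_exempt`, `evidence` (per-reaction
#'   motif hit tables) and `hits` (the full scan table).
#' @export
build_regulation <- function(utr_fasta, gene_map, net, min_repeats = 7L) {
  if (is.character(gene_map))
    gene_map <- read.delim(gene_map, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("sequence_id", "gene_id", "reaction_id")
  if (!all(needed %in% names(gene_map)))
    stop("gene_map must have columns: ", paste(needed, collapse = ", "))
  if (is.null(gene_map$isoform_group)) gene_map$isoform_group <- "1"
  seqs <- as_sequence_vector(utr_fasta)
  unmapped <- setdiff(names(seqs), gene_map$sequence_id)
  if (length(unmapped))
    warning("sequence id(s) with no gene mapping, skipped: ",
            paste(unmapped, collapse = ", "))
  unknown_rxn <- setdiff(gene_map$reaction_id, names(net$reactions))
  if (length(unknown_rxn))
    stop("gene_map references unknown reaction(s): ",
         paste(unknown_rxn, collapse = ", "))
  hits <- scan_utr_fasta(seqs, min_repeats)
  gene_has_hit <- function(g) {
    sids <- gene_map$sequence_id[gene_map$gene_id == g]
    any(hits$sequence_id %in% sids)
  }
  regulated <- character()
  exempt <- character()
  evidence <- list()
  for (rid in unique(gene_map$reaction_id)) {
    sub <- gene_map[gene_map$reaction_id == rid, , drop = FALSE]
    genes <- unique(sub$gene_id)
    if (length(genes) == 0L) next
    with_hit <- vapply(genes, gene_has_hit, logical(1))
    if (all(with_hit)) {
      regulated <- c(regulated, rid)
      evidence[[rid]] <- hits[hits$sequence_id %in% sub$sequence_id, , drop = FALSE]
    } else if (any(with_hit)) {
      exempt <- c(exempt, rid)
    }
  }
  no_gene <- setdiff(names(net$reactions), gene_map$reaction_id)
  if (length(no_gene))
    message(length(no_gene), " reaction(s) without mapped genes are unregulated")
  structure(
    list(regulated_reactions = sort(regulated),
         isoenzyme_exempt = sort(exempt),
         evidence = evidence, hits = hits, min_repeats = min_repeats),
    class = "regulation_annotation")
}

#' @export
print.regulation_annotation <- function(x, ...) {
  cat(sprintf("<regulation_annotation> %d regulated, %d isoenzyme-exempt reactions (min %d UG units)\n",
              length(x$regulated_reactions), length(x$isoenzyme_exempt),
              x$min_repeats))
  invisible(x)
}

#' Amino-acid composition of a proteome
#'
#' Pools all sequences of a protein FASTA and tallies residues. The twenty
#' standard one-letter codes are reported individually; ambiguity codes and
#' stops (B, J, O, U, Z, X, *) are tallied under `other` and excluded from
#' the percentage base.
#'
#' @param proteome_fasta Path to a protein FASTA, a named character vector,
#'   or an `AAStringSet`.
#' @return An object of class `composition_profile`: list with `counts`
#'   (named integer vector, 20 residues plus `other`), `percentages` (over
#'   the 20 standard residues, summing to 100) and `n_residues`.
#' @export
amino_acid_composition <- function(proteome_fasta) {
  seqs <- as_sequence_vector(proteome_fasta)
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L)
    stop("no protein sequences found")
  pooled <- toupper(paste(seqs, collapse = ""))
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(pooled, "")[[1]]
  nuc_share <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (nuc_share > 0.9)
    warning("input looks like nucleotide sequence (>90% ACGTUN)")
  tab <- table(factor(chars, levels = letters20))
  counts <- as.integer(tab)
  names(counts) <- letters20
  other <- length(chars) - sum(counts)
  counts <- c(counts, other = other)
  base <- sum(counts[letters20])
  if (base == 0L) stop("no standard amino-acid residues found")
  structure(
    list(counts = counts,
         percentages = 100 * counts[letters20] / base,
         n_residues = length(chars)),
    class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %d residues (%d non-standard)\n",
              x$n_residues, x$counts[["other"]]))
  print(round(x$percentages, 2))
  invisible(x)
}
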