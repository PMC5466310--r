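# Translation and codon-usage statistics under the invertebrate
# mitochondrial genetic code (NCBI translation table 5: AGA/AGG = Ser,
# ATA = Met, TGA = Trp; stops TAA and TAG only).

.mt_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("5")
    code
  }
})

.atn <- c("ATA", "ATT", "ATC", "ATG")
.stops <- c("TAA", "TAG")

.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
          "*" = "Stop")

#' Codon/family table of the invertebrate mitochondrial code
#'
#' All 64 codons with their amino acid and synonymous-family label.
#' Leucine and serine are split into the two-tRNA families used in
#' mitogenome work: `Leu1` = CTN, `Leu2` = TTA/TTG, `Ser1` = AGN,
#' `Ser2` = TCN. Stop codons carry family `Stop`.
#'
#' @return Data frame with columns `codon`, `aa` (1-letter), `family`.
#' @export
codon_family_table <- function() {
  code <- .mt_code()
  codons <- names(code)
  fam <- unname(.aa3[code])
  fam[substr(codons, 1, 2) == "CT"] <- "Leu1"
  fam[codons %in% c("TTA", "TTG")] <- "Leu2"
  fam[substr(codons, 1, 2) == "AG" & code == "S"] <- "Ser1"
  fam[substr(codons, 1, 2) == "TC"] <- "Ser2"
  data.frame(codon = codons, aa = unname(code), family = fam,
             stringsAsFactors = FALSE)
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  k <- n %/% 3L
  full <- if (k) substring(cds, 3L * seq_len(k) - 2L, 3L * seq_len(k))
          else character()
  list(codons = full, trailing = if (n %% 3L) substring(cds, 3L * k + 1L, n)
                                 else "")
}

#' Translate a mitochondrial coding sequence
#'
#' Translation under the invertebrate mitochondrial code. The first
#' codon is read as Met when it is one of the ATN alternative
#' initiators. A terminal stop codon is dropped from the peptide. With
#' `complete_stop = TRUE` a trailing partial codon of 1-2 bases is
#' permitted and completed with A's, modelling the polyadenylation that
#' turns an incomplete T/TA terminus into a functional TAA stop.
#'
#' @param cds Nucleotide string, length >= 3 (T or U).
#' @param complete_stop Allow and A-complete an incomplete terminal
#'   codon.
#' @return Amino-acid string (1-letter codes).
#' @export
translate_mt <- function(cds, complete_stop = FALSE) {
  cds <- chartr("u", "T", chartr("U", "T", toupper(cds)))
  if (nchar(cds) < 3L) stop("coding sequence shorter than one codon")
  if (grepl("[^ACGT]", cds)) stop("coding sequence contains non-ACGT characters")
  sp <- .split_codons(cds)
  if (nzchar(sp$trailing)) {
    if (!complete_stop)
      stop("sequence length ", nchar(cds),
           " is not a multiple of 3 (set complete_stop for an incomplete terminus)")
    completed <- paste0(sp$trailing, strrep("A", 3L - nchar(sp$trailing)))
    if (!completed %in% .stops)
      stop("incomplete terminal codon '", sp$trailing,
           "' does not complete to a stop by polyadenylation")
    sp$codons <- c(sp$codons, completed)
  }
  code <- .mt_code()
  aa <- unname(code[sp$codons])
  k <- length(aa)
  if (aa[k] == "*") { aa <- aa[-k]; k <- k - 1L }
  internal_stop <- which(aa == "*")
  if (length(internal_stop))
    stop("internal stop codon at codon position ", internal_stop[1])
  if (k >= 1L && sp$codons[1] %in% .atn) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Classify the start and stop codon of a protein-coding gene
#'
#' In table-only mode the printed codon columns are used; with sequence
#' present the codons are read off the extracted gene sequence. Start
#' class is `ATN` for the four alternative initiators, `nonstandard`
#' otherwise (e.g. the problematic cox1 start). Stop class is
#' `complete` for TAA/TAG, `incomplete_T` for a bare T and
#' `incomplete_TA` for TA.
#'
#' @param genome An [annotated_genome()].
#' @param record A PCG [gene_record()] of that genome.
#' @return An object of class `start_stop_call`: list with `gene`,
#'   `start_codon`, `start_class`, `stop_codon`, `stop_class`.
#' @export
classify_start_stop <- function(genome, record) {
  if (record$feature_class != "PCG")
    stop("'", record$name, "' is not a protein-coding gene")
  if (!is.null(genome$sequence)) {
    s <- extract_feature_sequence(genome, record)
    start_codon <- substring(s, 1L, 3L)
    rem <- nchar(s) %% 3L
    stop_codon <- if (rem == 0L) substring(s, nchar(s) - 2L, nchar(s))
                  else substring(s, nchar(s) - rem + 1L, nchar(s))
  } else {
    start_codon <- record$start_codon
    stop_codon <- record$stop_codon
    if (is.na(start_codon) || is.na(stop_codon))
      stop("printed codon columns missing for '", record$name,
           "' in table-only mode")
  }
  stop_class <- if (stop_codon %in% .stops) "complete"
    else if (stop_codon == "T") "incomplete_T"
    else if (stop_codon == "TA") "incomplete_TA"
    else stop("unrecognized stop codon '", stop_codon, "' for '",
              record$name, "'")
  structure(list(gene = record$name, start_codon = start_codon,
                 start_class = if (start_codon %in% .atn) "ATN" else "nonstandard",
                 stop_codon = stop_codon, stop_class = stop_class),
            class = "start_stop_call")
}

#' Start/stop codon tally over all protein-coding genes
#'
#' @param genome An [annotated_genome()].
#' @return List with `calls` (per-gene [classify_start_stop()] results),
#'   `start_tally` (named counts per start codon), `stop_tally` (named
#'   counts per stop class) and `incomplete_T_genes`.
#' @export
start_stop_tally <- function(genome) {
  pcgs <- Filter(function(r) r$feature_class == "PCG", genome$records)
  if (!length(pcgs)) stop("genome has no protein-coding genes")
  calls <- lapply(pcgs, function(r) classify_start_stop(genome, r))
  starts <- vapply(calls, `[[`, character(1), "start_codon")
  classes <- vapply(calls, `[[`, character(1), "stop_class")
  list(calls = calls,
       start_tally = table(starts),
       stop_tally = table(classes),
       incomplete_T_genes = vapply(
         calls[classes == "incomplete_T"], `[[`, character(1), "gene"))
}

#' Codon usage over a collection of coding sequences
#'
#' Counts codons over all sequences, excluding terminal stop codons and
#' incomplete (1-2 bp) terminal codons, and reports usage per thousand
#' codons (CDspT). Every sequence must translate cleanly (no internal
#' stops) under [translate_mt()].
#'
#' @param cds_collection Character vector or list of coding sequences.
#' @return An object of class `codon_usage`: list with `counts` (named
#'   over the 64 codons), `n_codons`, `per_thousand`, `family` (codon ->
#'   family label), `missing` (amino-acid codons with zero count) and an
#'   empty `rscu` slot filled by [rscu()].
#' @export
codon_usage <- function(cds_collection) {
  cds_collection <- as.character(unlist(cds_collection, use.names = FALSE))
  if (!length(cds_collection)) stop("empty coding-sequence collection")
  fam <- codon_family_table()
  counts <- stats::setNames(integer(64L), fam$codon)
  for (cds in cds_collection) {
    cds <- chartr("u", "T", chartr("U", "T", toupper(cds)))
    translate_mt(cds, complete_stop = TRUE)   # validates the frame
    sp <- .split_codons(cds)                   # trailing partial dropped
    codons <- sp$codons
    k <- length(codons)
    if (k && codons[k] %in% .stops) codons <- codons[-k]
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  n <- sum(counts)
  if (!n) stop("no codons counted")
  family <- stats::setNames(fam$family, fam$codon)
  aa_codons <- fam$codon[fam$family != "Stop"]
  structure(list(counts = counts, n_codons = n,
                 per_thousand = 1000 * counts / n,
                 family = family,
                 missing = aa_codons[counts[aa_codons] == 0L],
                 rscu = NULL),
            class = "codon_usage")
}

#' Relative synonymous codon usage
#'
#' `RSCU(codon) = count * family_size / family_total` within each
#' synonymous family (Leu and Ser split as in [codon_family_table()]).
#' Families with zero total, and the stop codons, are absent from the
#' result; within every reported family the mean RSCU is exactly 1.
#'
#' @param usage A `codon_usage` object from [codon_usage()].
#' @return The same object with the `rscu` slot filled (named numeric
#'   over codons of non-empty families).
#' @export
rscu <- function(usage) {
  stopifnot(inherits(usage, "codon_usage"))
  vals <- numeric(0)
  for (f in setdiff(unique(usage$family), "Stop")) {
    codons <- names(usage$family)[usage$family == f]
    tot <- sum(usage$counts[codons])
    if (tot == 0L) next
    v <- usage$counts[codons] * length(codons) / tot
    vals <- c(vals, stats::setNames(as.numeric(v), codons))
  }
  usage$rscu <- vals
  usage
}

#' Codon usage / RSCU report table
#'
#' @param usage A `codon_usage` object (run through [rscu()] if RSCU
#'   columns are wanted).
#' @param path Optional TSV output path.
#' @return Data frame with one row per codon: codon, amino acid, family,
#'   count, CDspT, RSCU (NA for stop codons and empty families) and a
#'   `missing` flag mirroring the "codon not present" annotation of
#'   published RSCU figures.
#' @export
codon_usage_report <- function(usage, path = NULL) {
  if (is.null(usage$rscu)) usage <- rscu(usage)
  fam <- codon_family_table()
  out <- data.frame(codon = fam$codon, aa = fam$aa, family = fam$family,
                    count = as.integer(usage$counts[fam$codon]),
                    CDspT = round(as.numeric(usage$per_thousand[fam$codon]), 2),
                    RSCU = round(as.numeric(usage$rscu[fam$codon]), 2),
                    missing = fam$codon %in% usage$missing,
                    stringsAsFactors = FALSE)
  out <- out[order(out$family, out$codon), ]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
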