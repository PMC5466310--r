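# Base composition and strand-skew statistics.
#
# Skew conventions: AT skew = (A - T) / (A + T), GC skew = (G - C) /
# (G + C), computed from raw counts of the strand under study.
# Percentages use unambiguous (ACGT) bases only as denominator;
# ambiguity codes are counted separately so that A% + C% + G% + T%
# always sums to 100.

#' AT skew and GC skew
#'
#' `(A - T) / (A + T)` and `(G - C) / (G + C)`; the arguments may be raw
#' counts or percentages (the ratio is scale-free).
#'
#' @param a,t,g,c Counts or percentages of the respective base.
#' @return Dimensionless signed skew in `[-1, 1]`.
#' @export
at_skew <- function(a, t) (a - t) / (a + t)

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) (g - c) / (g + c)

#' Base composition and skews of a nucleotide sequence
#'
#' @param seq Non-empty nucleotide string.
#' @return An object of class `composition`: a list with `n` (ACGT
#'   count), `n_ambiguous`, per-base `counts`, full-precision
#'   percentages `pct` and `pct_AT`, and `at_skew`/`gc_skew`.
#' @export
base_composition <- function(seq) {
  if (!nchar(seq)) stop("empty sequence")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), T = sum(chars == "T"))
  n <- sum(counts)
  if (n == 0L) stop("all-ambiguous sequence: composition undefined")
  pct <- 100 * counts / n
  structure(list(n = n, n_ambiguous = length(chars) - n, counts = counts,
                 pct = pct, pct_AT = unname(pct["A"] + pct["T"]),
                 at_skew = at_skew(counts[["A"]], counts[["T"]]),
                 gc_skew = gc_skew(counts[["G"]], counts[["C"]])),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf(
    "<composition> n=%d  A %.2f%%  C %.2f%%  G %.2f%%  T %.2f%%  A+T %.2f%%  ATskew %.3f  GCskew %.3f\n",
    x$n, x$pct["A"], x$pct["C"], x$pct["G"], x$pct["T"], x$pct_AT,
    x$at_skew, x$gc_skew))
  invisible(x)
}

#' Composition of a feature class of an annotated genome
#'
#' For `"whole"`, the composition of the full F strand. For a feature
#' class, the composition of the concatenated F-strand slices of every
#' feature of that class -- slices are taken from the F strand
#' regardless of the gene's own strand, and overlapping coverage is
#' counted once per feature, so class lengths add up the way annotation
#' tables sum them.
#'
#' @param genome An [annotated_genome()] with sequence present.
#' @param region_class `"whole"`, `"PCG"`, `"tRNA"`, `"rRNA"` or
#'   `"control_region"`.
#' @return A `composition` object (see [base_composition()]).
#' @export
region_composition <- function(genome, region_class = "whole") {
  if (is.null(genome$sequence))
    stop("genome '", genome$identifier,
         "' carries no sequence: composition needs sequence mode")
  region_class <- match.arg(region_class,
    c("whole", "PCG", "tRNA", "rRNA", "control_region"))
  if (region_class == "whole") return(base_composition(genome$sequence))
  recs <- Filter(function(r) r$feature_class == region_class, genome$records)
  if (!length(recs))
    stop("no features of class '", region_class, "' in genome '",
         genome$identifier, "'")
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  pieces <- vapply(recs, function(r)
    paste(chars[.circ_positions(r$start, r$end, genome$length)],
          collapse = ""), character(1))
  base_composition(paste(pieces, collapse = ""))
}

#' Total per-class feature length of an annotation table
#'
#' Coordinate-derived lengths summed per feature class (overlapping
#' coverage counted per feature). Works in table-only mode.
#'
#' @param genome An [annotated_genome()].
#' @return Named integer vector of summed lengths per class present.
#' @export
class_length_summary <- function(genome) {
  cls <- vapply(genome$records, function(r) r$feature_class, character(1))
  len <- vapply(genome$records, gene_length, integer(1),
                genome_length = genome$length)
  vapply(split(len, cls), sum, integer(1))
}

.panel_order <- c("whole" = "Whole genome", "PCG" = "PCG", "tRNA" = "tRNA",
                  "rRNA" = "rRNA", "control_region" = "A+T-rich region")

#' Multi-genome, multi-panel composition report
#'
#' One row per genome per panel (whole genome, PCG, tRNA, rRNA, A+T-rich
#' region), with percentages rounded to 2 decimals and skews to 3
#' decimals -- rounding happens only here, at the report boundary.
#' Panels whose class is absent from a genome are skipped.
#'
#' @param genomes A list of [annotated_genome()] objects with sequence.
#' @param path Optional TSV output path.
#' @return Data frame with columns `Species, Panel, Size_bp, A_pct,
#'   G_pct, T_pct, C_pct, AT_pct, ATskew, GCskew`.
#' @export
composition_report <- function(genomes, path = NULL) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  rows <- list()
  for (g in genomes) {
    for (cls in names(.panel_order)) {
      comp <- tryCatch(region_composition(g, cls), error = function(e) NULL)
      if (is.null(comp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        Species = g$identifier, Panel = .panel_order[[cls]], Size_bp = comp$n,
        A_pct = round(comp$pct[["A"]], 2), G_pct = round(comp$pct[["G"]], 2),
        T_pct = round(comp$pct[["T"]], 2), C_pct = round(comp$pct[["C"]], 2),
        AT_pct = round(comp$pct_AT, 2),
        ATskew = round(comp$at_skew, 3), GCskew = round(comp$gc_skew, 3),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
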