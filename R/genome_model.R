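#' @keywords internal
"_PACKAGE"

# Canonical column order of the annotation-table dialect.
.ann_cols <- c("Gene", "Direction", "Start", "End", "Size", "Anticodon",
               "StartCodon", "StopCodon", "IntergenicNucleotides")

# Names of the 13 mitochondrial protein-coding genes.
#' The 13 mitochondrial protein-coding genes
#'
#' Canonical names of the 13 protein-coding genes (PCGs) of the animal
#' mitogenome, in the genome order of the lepidopteran arrangement used
#' throughout this package.
#' @export
mt_pcg_names <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
                  "nad5", "nad4", "nad4L", "nad6", "cytb", "nad1")

#' Construct a single annotated gene record
#'
#' A `gene_record` is one row of a mitogenome annotation table: a named
#' feature with a strand, circular 1-based inclusive coordinates and the
#' codon/anticodon/intergenic values as printed in the source table.
#' Printed values (`size_printed`, `intergenic_printed`) are stored
#' verbatim and never silently corrected; [consistency_report()] flags
#' disagreements with the coordinate arithmetic.
#'
#' @param name Gene identifier, e.g. `"cox1"` or `"trnS1(AGN)"`.
#' @param feature_class One of `"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"control_region"`.
#' @param strand `"F"` (majority/H strand) or `"R"`.
#' @param start,end 1-based inclusive coordinates on the F strand.
#'   `start > end` is legal only for features wrapping the circular
#'   origin.
#' @param anticodon 3-letter anticodon for tRNAs, `NA` otherwise.
#' @param start_codon,stop_codon Codon strings for PCGs (`stop_codon`
#'   may be the incomplete `"T"` or `"TA"`), `NA` otherwise.
#' @param size_printed,intergenic_printed The values printed in the
#'   source table, or `NA`.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(name, feature_class, strand, start, end,
                        anticodon = NA_character_,
                        start_codon = NA_character_,
                        stop_codon = NA_character_,
                        size_printed = NA_integer_,
                        intergenic_printed = NA_integer_) {
  feature_class <- match.arg(feature_class,
                             c("PCG", "tRNA", "rRNA", "control_region"))
  if (!strand %in% c("F", "R"))
    stop("unknown strand symbol '", strand, "' for gene '", name, "'")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L)
    stop("invalid coordinates for gene '", name, "'")
  if (feature_class == "tRNA" && is.na(anticodon))
    stop("tRNA record '", name, "' requires an anticodon")
  if (feature_class != "tRNA" && !is.na(anticodon))
    stop("anticodon given for non-tRNA record '", name, "'")
  if (feature_class == "PCG" && is.na(start_codon))
    stop("PCG record '", name, "' requires a start codon")
  if (feature_class != "PCG" && !is.na(start_codon))
    stop("start codon given for non-PCG record '", name, "'")
  structure(list(name = name, feature_class = feature_class,
                 strand = strand, start = start, end = end,
                 wraps = start > end,
                 anticodon = if (is.na(anticodon)) NA_character_ else toupper(anticodon),
                 start_codon = if (is.na(start_codon)) NA_character_ else toupper(start_codon),
                 stop_codon = if (is.na(stop_codon)) NA_character_ else toupper(stop_codon),
                 size_printed = as.integer(size_printed),
                 intergenic_printed = as.integer(intergenic_printed)),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s [%s] %s %d-%d%s\n", x$name,
              x$feature_class, x$strand, x$start, x$end,
              if (x$wraps) " (wraps origin)" else ""))
  invisible(x)
}

#' Construct an annotated (optionally sequence-bearing) circular genome
#'
#' @param identifier Taxon label.
#' @param records List of [gene_record()] objects, in genome order.
#' @param length Genome length in bp. Defaults to the maximum `end`
#'   coordinate over the records (table-only mode).
#' @param sequence F-strand nucleotide string of length `length`, or
#'   `NULL` in table-only mode.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(identifier, records, length = NULL,
                             sequence = NULL) {
  stopifnot(is.list(records))
  if (is.null(length)) {
    # max coordinate seen: the end column, except that a wrapping
    # feature's start may be the largest position on the circle
    length <- if (!base::length(records)) 0L else
      max(vapply(records, function(r) max(r$start, r$end), integer(1)))
  }
  length <- as.integer(length)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not equal the declared genome length (", length, ")")
    if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
      stop("sequence contains non-IUPAC characters")
  }
  for (r in records) {
    if (r$start > length || r$end > length)
      stop("record '", r$name, "' has coordinates beyond genome length ",
           length)
  }
  structure(list(identifier = identifier, length = length,
                 sequence = sequence, records = records),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cls <- table(vapply(x$records, function(r) r$feature_class, character(1)))
  cat(sprintf("<annotated_genome> %s: %d bp (circular), %d features%s\n",
              x$identifier, x$length, length(x$records),
              if (is.null(x$sequence)) " [table-only]" else ""))
  if (length(cls)) print(cls)
  invisible(x)
}

# Infer the feature class of an annotation-table row from its fields.
.infer_class <- function(name, anticodon, start_codon) {
  if (!is.na(anticodon)) return("tRNA")
  if (!is.na(start_codon)) return("PCG")
  if (grepl("^rrn", name)) return("rRNA")
  "control_region"
}

.na_dash <- function(x) {
  x <- trimws(x)
  x[x %in% c("-", "—", "–", "")] <- NA_character_
  x
}

#' Read a mitogenome annotation table
#'
#' Reads the tab-separated annotation-table dialect used throughout the
#' package (columns `Gene, Direction, Start, End, Size, Anticodon,
#' StartCodon, StopCodon, IntergenicNucleotides`; `-` marks an absent
#' value). The feature class of each row is inferred: rows with an
#' anticodon are tRNAs, rows with a start codon are PCGs, names starting
#' `rrn` are rRNAs and everything else is a control region. Row order is
#' preserved and the genome length is set to the maximum end coordinate.
#'
#' @param path Path to the TSV file.
#' @param identifier Taxon label for the resulting genome; defaults to
#'   the file base name.
#' @return An [annotated_genome()] without sequence (table-only mode).
#' @seealso [write_annotation_table()], [consistency_report()]
#' @export
read_annotation_table <- function(path, identifier = NULL) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (!all(.ann_cols %in% names(tab)))
    stop("annotation table misses columns: ",
         paste(setdiff(.ann_cols, names(tab)), collapse = ", "))
  if (is.null(identifier))
    identifier <- sub("\\.[^.]*$", "", basename(path))
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- lapply(tab[i, .ann_cols], .na_dash)
    for (fld in c("Start", "End", "Size", "IntergenicNucleotides")) {
      v <- row[[fld]]
      if (!is.na(v) && is.na(suppressWarnings(as.integer(v))))
        stop("malformed ", fld, " field '", v, "' in row ", i,
             " (gene '", row$Gene, "')")
    }
    if (is.na(row$Gene)) stop("missing gene name in row ", i)
    strand <- if (is.na(row$Direction)) "F" else row$Direction
    cls <- .infer_class(row$Gene, row$Anticodon, row$StartCodon)
    records[[i]] <- gene_record(
      name = row$Gene, feature_class = cls, strand = strand,
      start = as.integer(row$Start), end = as.integer(row$End),
      anticodon = row$Anticodon, start_codon = row$StartCodon,
      stop_codon = row$StopCodon,
      size_printed = suppressWarnings(as.integer(row$Size)),
      intergenic_printed = suppressWarnings(as.integer(row$IntergenicNucleotides)))
  }
  annotated_genome(identifier, records)
}

#' Write a mitogenome annotation table
#'
#' Inverse of [read_annotation_table()]: `read(write(g))` reproduces the
#' records exactly.
#'
#' @param genome An [annotated_genome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(genome, path) {
  fmt <- function(x) ifelse(is.na(x), "-", as.character(x))
  rows <- vapply(genome$records, function(r) {
    paste(c(r$name, r$strand, r$start, r$end, fmt(r$size_printed),
            fmt(r$anticodon), fmt(r$start_codon), fmt(r$stop_codon),
            fmt(r$intergenic_printed)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(.ann_cols, collapse = "\t"), rows), path)
  invisible(path)
}

#' Length of an annotated feature on a circular genome
#'
#' `end - start + 1` for ordinary features; features wrapping the
#' circular origin (`start > end`) span
#' `(genome_length - start + 1) + end` bases.
#'
#' @param record A [gene_record()].
#' @param genome_length Genome length in bp.
#' @return Integer length in bp.
#' @export
gene_length <- function(record, genome_length) {
  if (record$start > genome_length || record$end > genome_length)
    stop("coordinates of '", record$name, "' out of range for length ",
         genome_length)
  if (record$start <= record$end)
    record$end - record$start + 1L
  else
    (genome_length - record$start + 1L) + record$end
}

# 1-based circular position vector covered by a record, in strand-F order.
.circ_positions <- function(start, end, genome_length) {
  if (start <= end) start:end
  else c(start:genome_length, 1:end)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string (IUPAC codes allowed).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Extract the nucleotide sequence of an annotated feature
#'
#' Circular-aware slice of the F strand; features on the R strand are
#' returned reverse-complemented so the result always reads 5'->3' on
#' the coding strand.
#'
#' @param genome An [annotated_genome()] with sequence present.
#' @param record A [gene_record()] of that genome.
#' @return Nucleotide string of length [gene_length()].
#' @export
extract_feature_sequence <- function(genome, record) {
  if (is.null(genome$sequence))
    stop("genome '", genome$identifier,
         "' carries no sequence: operation unsupported in table-only mode")
  pos <- .circ_positions(record$start, record$end, genome$length)
  s <- paste(strsplit(genome$sequence, "", fixed = TRUE)[[1]][pos],
             collapse = "")
  if (record$strand == "R") revcomp(s) else s
}

#' Report printed-vs-computed inconsistencies of an annotation table
#'
#' Published annotation tables occasionally disagree with their own
#' coordinates. This report lists, without correcting anything, every
#' record whose printed `Size` differs from the coordinate-derived
#' length, and every adjacent pair whose printed intergenic value
#' differs from the coordinate-derived gap.
#'
#' @param genome An [annotated_genome()].
#' @return A data frame with columns `kind` (`"size"` or
#'   `"intergenic"`), `gene`, `printed`, `computed`.
#' @export
consistency_report <- function(genome) {
  out <- data.frame(kind = character(), gene = character(),
                    printed = integer(), computed = integer(),
                    stringsAsFactors = FALSE)
  for (r in genome$records) {
    if (!is.na(r$size_printed)) {
      len <- gene_length(r, genome$length)
      if (len != r$size_printed)
        out[nrow(out) + 1L, ] <- list("size", r$name, r$size_printed, len)
    }
  }
  led <- pair_ledger(genome, source = "coordinates")
  for (i in seq_along(genome$records)) {
    r <- genome$records[[i]]
    if (is.na(r$intergenic_printed)) next
    comp <- led$gap[led$upstream == r$name]
    if (length(comp) == 1L && comp != r$intergenic_printed)
      out[nrow(out) + 1L, ] <- list("intergenic", r$name,
                                    r$intergenic_printed, comp)
  }
  out
}
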