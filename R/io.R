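# FASTA and GenBank flat-file I/O.
#
# FASTA goes through Biostrings. The GenBank reader/writer below covers
# the minimal organelle-genome dialect this pipeline emits and consumes
# (LOCUS with circular DNA, features CDS/tRNA/rRNA/D-loop with /gene
# qualifiers, ORIGIN block); no installed R package parses GenBank flat
# files, hence the small hand parser.

#' Read a single-record FASTA file
#'
#' @param path Path to a FASTA file holding exactly one record.
#' @return List with `identifier` (first word of the header) and
#'   `sequence` (upper-case nucleotide string).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("expected a single-record FASTA, found ", length(set), " records")
  list(identifier = strsplit(names(set)[1], "\\s+")[[1]][1],
       sequence = toupper(as.character(set[[1]])))
}

#' Write a single-record FASTA file
#'
#' @param identifier Header label.
#' @param sequence Nucleotide string.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(identifier, sequence, path, width = 70L) {
  n <- nchar(sequence)
  starts <- seq(1L, max(n, 1L), by = width)
  lines <- substring(sequence, starts, pmin(starts + width - 1L, n))
  writeLines(c(paste0(">", identifier), lines), path)
  invisible(path)
}

.gb_feature_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     control_region = "D-loop")

#' Write a GenBank flat file for an annotated genome
#'
#' Feature keys: PCG -> `CDS`, tRNA -> `tRNA`, rRNA -> `rRNA`, control
#' region -> `D-loop`. R-strand features use `complement(..)` locations;
#' origin-wrapping features use `join(..)`. Codon and anticodon values
#' are carried in `/note` qualifiers so that reading the file back
#' reconstructs the records.
#'
#' @param genome An [annotated_genome()] with sequence present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  if (is.null(genome$sequence))
    stop("cannot write GenBank without a sequence")
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %s %d bp    DNA     circular INV %s",
    genome$identifier, genome$length, format(Sys.Date(), "%d-%b-%Y"))
  w("DEFINITION  %s mitochondrion, complete genome.", genome$identifier)
  w("FEATURES             Location/Qualifiers")
  loc_str <- function(r) {
    base <- if (r$wraps)
      sprintf("join(%d..%d,1..%d)", r$start, genome$length, r$end)
    else sprintf("%d..%d", r$start, r$end)
    if (r$strand == "R") sprintf("complement(%s)", base) else base
  }
  w("     source          1..%d", genome$length)
  for (r in genome$records) {
    w("     %-16s%s", .gb_feature_key[[r$feature_class]], loc_str(r))
    w("                     /gene=\"%s\"", r$name)
    notes <- character()
    if (!is.na(r$anticodon)) notes <- c(notes, paste0("anticodon:", r$anticodon))
    if (!is.na(r$start_codon)) notes <- c(notes, paste0("start_codon:", r$start_codon))
    if (!is.na(r$stop_codon)) notes <- c(notes, paste0("stop_codon:", r$stop_codon))
    if (!is.na(r$size_printed)) notes <- c(notes, paste0("size_printed:", r$size_printed))
    if (!is.na(r$intergenic_printed))
      notes <- c(notes, paste0("intergenic_printed:", r$intergenic_printed))
    if (length(notes))
      w("                     /note=\"%s\"", paste(notes, collapse = ";"))
  }
  w("ORIGIN")
  s <- tolower(genome$sequence)
  for (i in seq(1L, nchar(s), by = 60L)) {
    chunk <- substring(s, i, min(i + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(1L, nchar(chunk), 10L) + 9L, nchar(chunk)))
    w("%9d %s", i, paste(groups, collapse = " "))
  }
  w("//")
  invisible(path)
}

#' Read a GenBank flat file into an annotated genome
#'
#' Parses the minimal dialect written by [write_genbank()]: LOCUS length,
#' gene/CDS/tRNA/rRNA/D-loop features (a `gene` feature paired with a
#' typed feature at the same location is collapsed onto the typed one),
#' `complement()`/`join()` locations, `/gene` and `/note` qualifiers and
#' the ORIGIN sequence block.
#'
#' @param path Path to the GenBank file.
#' @return An [annotated_genome()] with sequence present.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("no LOCUS line in ", path)
  m <- regmatches(locus[1],
                  regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp", locus[1]))[[1]]
  if (length(m) < 3L) stop("LOCUS line lacks a length in bp")
  identifier <- m[2]; glen <- as.integer(m[3])

  ori <- grep("^ORIGIN", lines)
  seq_txt <- ""
  if (length(ori)) {
    body <- lines[(ori[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq_txt <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    if (grepl("[^ACGTRYSWKMBDHVN]", seq_txt))
      stop("ORIGIN block contains non-nucleotide characters")
  }

  feat_start <- grep("^FEATURES", lines)
  feat_end <- if (length(ori)) ori[1] - 1L else length(lines)
  records <- list()
  if (length(feat_start)) {
    flines <- lines[(feat_start[1] + 1L):feat_end]
    # split into feature blocks: a block starts at column 6 with a key
    key_idx <- grep("^     \\S", flines)
    for (bi in seq_along(key_idx)) {
      from <- key_idx[bi]
      to <- if (bi < length(key_idx)) key_idx[bi + 1L] - 1L else length(flines)
      block <- flines[from:to]
      key <- sub("^\\s*(\\S+).*", "\\1", block[1])
      if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop")) next
      loc <- sub("^\\s*\\S+\\s+", "", block[1])
      strand <- "F"
      if (grepl("^complement\\(", loc)) {
        strand <- "R"; loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      wraps <- grepl("^join\\(", loc)
      if (wraps) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
      nums <- as.integer(unlist(regmatches(loc, gregexpr("\\d+", loc))))
      if (length(nums) < 2L) stop("unparseable location '", loc, "'")
      start <- nums[1]
      end <- nums[length(nums)]
      quals <- paste(block[-1], collapse = " ")
      getq <- function(q) {
        mm <- regmatches(quals, regexec(paste0("/", q, "=\"([^\"]*)\""), quals))[[1]]
        if (length(mm) == 2L) mm[2] else NA_character_
      }
      name <- getq("gene")
      if (is.na(name)) name <- paste0(key, "_", start)
      note <- getq("note")
      notes <- if (is.na(note)) character() else strsplit(note, ";")[[1]]
      getn <- function(k) {
        hit <- grep(paste0("^", k, ":"), notes, value = TRUE)
        if (length(hit)) sub(paste0("^", k, ":"), "", hit[1]) else NA_character_
      }
      cls <- names(.gb_feature_key)[match(key, .gb_feature_key)]
      records[[length(records) + 1L]] <- gene_record(
        name = name, feature_class = cls, strand = strand,
        start = start, end = end,
        anticodon = getn("anticodon"), start_codon = getn("start_codon"),
        stop_codon = getn("stop_codon"),
        size_printed = suppressWarnings(as.integer(getn("size_printed"))),
        intergenic_printed = suppressWarnings(as.integer(getn("intergenic_printed"))))
    }
  }
  annotated_genome(identifier, records, length = glen,
                   sequence = if (nzchar(seq_txt)) seq_txt else NULL)
}
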