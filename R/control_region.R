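# Motif, homopolymer, microsatellite and perfect-tandem-repeat
# detection in the A+T-rich control region and intergenic spacers.
#
# Repeat semantics shared by all detectors (and mirrored by the
# exhaustive test oracle): a hit for unit length u is a maximal run of
# period u whose starting unit is primitive (not itself a repetition),
# with copies = length / u, possibly fractional for a partial final
# unit. Only perfect repeats are detected; alignment-scored imperfect
# repeats (tandem repeats finder style) are out of scope.

.check_motif <- function(motif) {
  motif <- toupper(motif)
  if (nchar(motif) < 3L) stop("motif shorter than 3 bases")
  if (grepl("[^ACGT]", motif))
    stop("motif contains ambiguous characters: '", motif, "'")
  motif
}

.motif_starts <- function(region, motif) {
  # all (possibly overlapping) exact occurrences
  m <- gregexpr(paste0("(?=", motif, ")"), region, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

.context_of <- function(region, start, end, width = 5L) {
  n <- nchar(region)
  paste0(substring(region, max(1L, start - width), start - 1L), "[",
         substring(region, start, end), "]",
         substring(region, end + 1L, min(n, end + width)))
}

#' Find exact occurrences of a motif
#'
#' All (possibly overlapping) exact occurrences of `motif`, on the F
#' strand and -- with `both_strands = TRUE` -- of its reverse complement,
#' reported in F-strand coordinates with strand `"R"`.
#'
#' @param region Nucleotide string to scan.
#' @param motif ACGT-only motif, length >= 3.
#' @param both_strands Also scan the reverse strand.
#' @return Data frame with columns `motif`, `strand`, `start`, `end`,
#'   `context`; zero rows when absent.
#' @export
find_motif <- function(region, motif, both_strands = FALSE) {
  region <- toupper(region)
  motif <- .check_motif(motif)
  w <- nchar(motif)
  build <- function(starts, strand) {
    if (!length(starts))
      return(data.frame(motif = character(), strand = character(),
                        start = integer(), end = integer(),
                        context = character(), stringsAsFactors = FALSE))
    data.frame(motif = motif, strand = strand, start = starts,
               end = starts + w - 1L,
               context = vapply(starts, function(s)
                 .context_of(region, s, s + w - 1L), character(1)),
               stringsAsFactors = FALSE)
  }
  out <- build(.motif_starts(region, motif), "F")
  if (both_strands)
    out <- rbind(out, build(.motif_starts(region, revcomp(motif)), "R"))
  rownames(out) <- NULL
  out
}

#' Longest homopolymer run of a base
#'
#' @param region Nucleotide string.
#' @param base Single base.
#' @return A one-row data frame (`unit`, `copies`, `start`, `end`,
#'   `kind = "homopolymer"`); zero rows if the base never occurs. Ties
#'   are broken by first occurrence.
#' @export
longest_homopolymer <- function(region, base) {
  chars <- strsplit(toupper(region), "", fixed = TRUE)[[1]]
  r <- rle(chars == toupper(base))
  hit <- which(r$values)
  if (!length(hit))
    return(data.frame(unit = character(), copies = numeric(),
                      start = integer(), end = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  lens <- r$lengths[hit]
  i <- hit[which.max(lens)]
  start <- if (i == 1L) 1L else sum(r$lengths[seq_len(i - 1L)]) + 1L
  data.frame(unit = toupper(base), copies = as.numeric(max(lens)),
             start = start, end = start + max(lens) - 1L,
             kind = "homopolymer", stringsAsFactors = FALSE)
}

.is_primitive <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (strrep(substring(unit, 1L, d), u %/% d) == unit) return(FALSE)
  }
  TRUE
}

.least_rotation <- function(unit) {
  u <- nchar(unit)
  rots <- vapply(seq_len(u), function(k)
    paste0(substring(unit, k, u), substring(unit, 1L, k - 1L)), character(1))
  sort(rots)[1]
}

# Core scanner: maximal perfect period-u runs with primitive starting
# unit, one hit per (u, leftmost start).
.perfect_repeats <- function(region, unit_sizes, min_copies) {
  chars <- strsplit(toupper(region), "", fixed = TRUE)[[1]]
  n <- length(chars)
  hits <- list()
  for (u in sort(unique(as.integer(unit_sizes)))) {
    if (u < 1L || u > n) next
    i <- 1L
    while (i + u - 1L <= n) {
      # left-maximality: extending to i-1 must break the period
      if (i > 1L && i + u - 1L <= n && chars[i - 1L] == chars[i + u - 1L]) {
        i <- i + 1L; next
      }
      j <- i + u - 1L
      while (j + 1L <= n && chars[j + 1L] == chars[j + 1L - u]) j <- j + 1L
      len <- j - i + 1L
      copies <- len / u
      unit <- paste(chars[i:(i + u - 1L)], collapse = "")
      if (copies >= min_copies && .is_primitive(unit)) {
        hits[[length(hits) + 1L]] <- data.frame(
          unit = .least_rotation(unit), unit_observed = unit,
          unit_size = u, copies = copies, start = i, end = j,
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (!length(hits))
    return(data.frame(unit = character(), unit_observed = character(),
                      unit_size = integer(), copies = numeric(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$unit_size), ]
  rownames(out) <- NULL
  out
}

#' Find perfect microsatellite arrays
#'
#' Maximal perfect tandem arrays of any unit of the given sizes with at
#' least `min_copies` copies (a partial final unit contributes
#' fractional copies). Units are canonicalized to their
#' lexicographically least rotation; homopolymers are only reported
#' under unit size 1 (larger non-primitive units are skipped).
#'
#' @param region Nucleotide string.
#' @param unit_sizes Integer vector of unit lengths (>= 1).
#' @param min_copies Minimum copy number (>= 3).
#' @return Data frame with columns `unit`, `unit_observed`, `unit_size`,
#'   `copies`, `start`, `end`, `kind`.
#' @export
find_microsatellites <- function(region, unit_sizes = 1:6, min_copies = 3) {
  stopifnot(all(unit_sizes >= 1L), min_copies >= 3)
  out <- .perfect_repeats(region, unit_sizes, min_copies)
  out$kind <- ifelse(out$unit_size == 1L, "homopolymer", "microsatellite")
  out
}

#' Find perfect tandem repeats with nested-report suppression
#'
#' Same detector as [find_microsatellites()] over unit lengths
#' `min_unit..max_unit`, but arrays whose span lies inside the span of
#' an array with a longer unit are suppressed (longest unit wins, ties
#' to the leftmost).
#'
#' @param region Nucleotide string.
#' @param min_unit,max_unit Unit-length range; `max_unit` longer than
#'   the region is clamped with a warning.
#' @param min_copies Minimum copy number.
#' @return Data frame as in [find_microsatellites()], `kind = "tandem"`.
#' @export
find_tandem_repeats <- function(region, min_unit = 1L, max_unit = 6L,
                                min_copies = 3) {
  n <- nchar(region)
  if (max_unit > n) {
    warning("max_unit clamped to region length ", n)
    max_unit <- n
  }
  out <- .perfect_repeats(region, min_unit:max_unit, min_copies)
  if (nrow(out) > 1L) {
    ord <- order(-out$unit_size, out$start)
    keep <- logical(nrow(out))
    spans <- list()
    for (i in ord) {
      contained <- any(vapply(spans, function(sp)
        out$start[i] >= sp[1] && out$end[i] <= sp[2], logical(1)))
      if (!contained) {
        keep[i] <- TRUE
        spans[[length(spans) + 1L]] <- c(out$start[i], out$end[i])
      }
    }
    out <- out[keep, ]
  }
  out$kind <- rep("tandem", nrow(out))
  rownames(out) <- NULL
  out
}

#' Find the ATAGA / poly-T element of the A+T-rich region
#'
#' Looks for an occurrence of `motif` (default ATAGA) whose downstream
#' run of T -- starting within `offset_max` bases of the motif end --
#' reaches at least `min_len` bases. With `min_len = 0` this degenerates
#' to plain motif finding.
#'
#' @param region Nucleotide string (scanned as given; run it on the
#'   reverse complement if your control region is stored on the other
#'   strand).
#' @param motif Anchor motif (default `"ATAGA"`).
#' @param offset_max Allowed gap (0-2 bp typical) between motif end and
#'   poly-T start.
#' @param min_len Minimum poly-T length.
#' @return `NULL` when absent, else a list with `motif` (one-row hit
#'   data frame), `polyT` (one-row repeat data frame) and `offset`.
#' @export
find_ataga_polyT <- function(region, motif = "ATAGA", offset_max = 2L,
                             min_len = 10L) {
  region <- toupper(region)
  hits <- find_motif(region, motif)
  if (!nrow(hits)) return(NULL)
  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  n <- length(chars)
  for (h in seq_len(nrow(hits))) {
    e <- hits$end[h]
    for (off in 0:offset_max) {
      s <- e + 1L + off
      if (s > n || chars[s] != "T") next
      j <- s
      while (j + 1L <= n && chars[j + 1L] == "T") j <- j + 1L
      if (j - s + 1L >= min_len) {
        return(list(motif = hits[h, , drop = FALSE],
                    polyT = data.frame(unit = "T", copies = as.numeric(j - s + 1L),
                                       start = s, end = j,
                                       kind = "homopolymer",
                                       stringsAsFactors = FALSE),
                    offset = off))
      }
    }
    if (min_len == 0L)
      return(list(motif = hits[h, , drop = FALSE], polyT = NULL, offset = NA_integer_))
  }
  NULL
}

#' Scan spacers and the control region for conserved elements
#'
#' Every intergenic spacer of at least `min_spacer_len` bp is scanned
#' for the motifs in `motifs` (defaults: the mtTERM-associated ATACTAA
#' and the atp8/atp6 junction motif ATGATAA); the A+T-rich region is
#' scanned for the ATAGA/poly-T element, (AT)-type microsatellites and
#' the longest poly-A stretch. Coordinates are genome-global.
#'
#' @param genome An [annotated_genome()] with sequence.
#' @param motifs Motif list for spacers (may be empty).
#' @param min_spacer_len Minimum spacer length scanned.
#' @param polyT_min Minimum poly-T length for the ATAGA element.
#' @param ms_min_copies Minimum copies for microsatellite reporting.
#' @param path Optional TSV output path.
#' @return Data frame with columns `region`, `kind`, `motif`, `copies`,
#'   `strand`, `start`, `end` (one row per hit).
#' @export
spacer_motif_report <- function(genome, motifs = c("ATACTAA", "ATGATAA"),
                                min_spacer_len = 10L, polyT_min = 10L,
                                ms_min_copies = 5, path = NULL) {
  if (is.null(genome$sequence))
    stop("genome '", genome$identifier,
         "' carries no sequence: motif scanning needs sequence mode")
  empty <- data.frame(region = character(), kind = character(),
                      motif = character(), copies = numeric(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rows <- list(empty)
  add <- function(region, kind, motif, copies, strand, start, end) {
    rows[[length(rows) + 1L]] <<- data.frame(
      region = region, kind = kind, motif = motif, copies = copies,
      strand = strand, start = start, end = end, stringsAsFactors = FALSE)
  }
  led <- pair_ledger(genome, "coordinates")
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(led))) {
    if (led$gap[i] < min_spacer_len) next
    up <- .find_record(genome, led$upstream[i])
    pos <- ((up$end + seq_len(led$gap[i]) - 1L) %% genome$length) + 1L
    spacer <- paste(chars[pos], collapse = "")
    label <- paste0("spacer:", led$upstream[i], "-", led$downstream[i])
    for (m in motifs) {
      hits <- find_motif(spacer, m, both_strands = TRUE)
      for (h in seq_len(nrow(hits)))
        add(label, "motif", m, 1, hits$strand[h],
            pos[hits$start[h]], pos[hits$end[h]])
    }
  }
  cr <- Filter(function(r) r$feature_class == "control_region",
               genome$records)
  if (length(cr)) {
    r <- cr[[1]]
    pos <- .circ_positions(r$start, r$end, genome$length)
    region <- paste(chars[pos], collapse = "")
    el <- find_ataga_polyT(region, min_len = polyT_min)
    if (!is.null(el)) {
      add("control_region", "motif", el$motif$motif[1], 1, "F",
          pos[el$motif$start[1]], pos[el$motif$end[1]])
      if (!is.null(el$polyT))
        add("control_region", "polyT", "T", el$polyT$copies[1], "F",
            pos[el$polyT$start[1]], pos[el$polyT$end[1]])
    }
    ms <- find_microsatellites(region, unit_sizes = 2L,
                               min_copies = ms_min_copies)
    for (h in seq_len(nrow(ms)))
      add("control_region", "microsatellite", ms$unit[h], ms$copies[h],
          "F", pos[ms$start[h]], pos[ms$end[h]])
    pa <- longest_homopolymer(region, "A")
    if (nrow(pa))
      add("control_region", "polyA", "A", pa$copies[1], "F",
          pos[pa$start[1]], pos[pa$end[1]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
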