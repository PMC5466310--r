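# Adjacent-gene accounting on the circle: overlaps (negative gaps),
# intergenic spacers (positive gaps), and gene-order comparison.

#' Ledger of gaps between adjacent genes
#'
#' One entry per adjacent pair in genome order. In `"coordinates"` mode
#' the gap is `start(downstream) - end(upstream) - 1`, computed modulo
#' the circular genome length (the representative closest to zero is
#' reported, so overlaps come out negative), and the circular closing
#' pair (last feature -> first feature) is included unless
#' `include_closing = FALSE`. In `"printed"` mode the printed
#' intergenic-nucleotide column is copied verbatim, attributed to the
#' row's gene as the upstream member; rows without a printed value
#' contribute no entry, which reproduces published summaries that carry
#' no closing entry.
#'
#' @param genome An [annotated_genome()] with >= 2 records.
#' @param source `"printed"` or `"coordinates"`.
#' @param include_closing Include the circular closing pair
#'   (coordinates mode only).
#' @return Data frame with columns `upstream`, `downstream`, `gap`,
#'   `source`.
#' @export
pair_ledger <- function(genome, source = c("coordinates", "printed"),
                        include_closing = TRUE) {
  source <- match.arg(source)
  recs <- genome$records
  n <- length(recs)
  if (n < 2L) stop("need at least two records for a pair ledger")
  up <- vapply(recs, `[[`, character(1), "name")
  down <- up[c(2:n, 1L)]
  if (source == "printed") {
    printed <- vapply(recs, `[[`, integer(1), "intergenic_printed")
    if (all(is.na(printed)))
      stop("printed mode requires the intergenic-nucleotides column")
    keep <- !is.na(printed)
    out <- data.frame(upstream = up[keep], downstream = down[keep],
                      gap = printed[keep], source = "printed",
                      stringsAsFactors = FALSE)
  } else {
    L <- genome$length
    ends <- vapply(recs, `[[`, integer(1), "end")
    starts <- vapply(recs, `[[`, integer(1), "start")
    gap <- (starts[c(2:n, 1L)] - ends - 1L) %% L
    gap <- ifelse(gap > L / 2, gap - L, gap)   # overlaps are negative
    out <- data.frame(upstream = up, downstream = down, gap = as.integer(gap),
                      source = "coordinates", stringsAsFactors = FALSE)
    if (!include_closing) out <- out[-n, ]
  }
  rownames(out) <- NULL
  out
}

#' Summary statistics of a pair ledger
#'
#' @param ledger A data frame from [pair_ledger()].
#' @param major_cutoff Spacer length (bp) counted as "major"
#'   (default 10).
#' @return An object of class `topology_summary`: counts, total bp and
#'   first-occurrence maxima for overlaps and spacers, plus the number
#'   of spacers at least `major_cutoff` bp.
#' @export
summarize_topology <- function(ledger, major_cutoff = 10L) {
  if (!nrow(ledger)) stop("empty ledger")
  ov <- ledger[ledger$gap < 0L, , drop = FALSE]
  sp <- ledger[ledger$gap > 0L, , drop = FALSE]
  first_max <- function(d, v) {
    if (!nrow(d)) return(list(bp = 0L, pair = c(NA_character_, NA_character_)))
    i <- which.max(v)   # first occurrence wins ties
    list(bp = v[i], pair = c(d$upstream[i], d$downstream[i]))
  }
  mo <- first_max(ov, -ov$gap)
  ms <- first_max(sp, sp$gap)
  structure(list(
    n_overlaps = nrow(ov), overlap_total_bp = sum(-ov$gap),
    overlap_max_bp = mo$bp, overlap_max_pair = mo$pair,
    n_spacers = nrow(sp), spacer_total_bp = sum(sp$gap),
    spacer_max_bp = ms$bp, spacer_max_pair = ms$pair,
    n_major_spacers = sum(sp$gap >= major_cutoff),
    major_cutoff = as.integer(major_cutoff)), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("<topology_summary> %d overlaps (%d bp, max %d at %s-%s); %d spacers (%d bp, max %d at %s-%s); %d spacers >= %d bp\n",
              x$n_overlaps, x$overlap_total_bp, x$overlap_max_bp,
              x$overlap_max_pair[1], x$overlap_max_pair[2],
              x$n_spacers, x$spacer_total_bp, x$spacer_max_bp,
              x$spacer_max_pair[1], x$spacer_max_pair[2],
              x$n_major_spacers, x$major_cutoff))
  invisible(x)
}

.find_record <- function(genome, name) {
  for (r in genome$records) if (r$name == name) return(r)
  stop("gene '", name, "' not found in genome '", genome$identifier, "'")
}

#' Sequence shared by two overlapping genes
#'
#' Returns the F-strand slice of the positions covered by both members
#' of an overlapping adjacent pair (circular-aware).
#'
#' @param genome An [annotated_genome()] with sequence.
#' @param pair Character vector of the two gene names (upstream,
#'   downstream).
#' @return Nucleotide string of the overlap.
#' @export
motif_at_overlap <- function(genome, pair) {
  if (is.null(genome$sequence)) stop("sequence required")
  a <- .find_record(genome, pair[1])
  b <- .find_record(genome, pair[2])
  pa <- .circ_positions(a$start, a$end, genome$length)
  pb <- .circ_positions(b$start, b$end, genome$length)
  shared <- pb[pb %in% pa]   # in downstream order, a contiguous slice
  if (!length(shared))
    stop("genes '", pair[1], "' and '", pair[2], "' do not overlap")
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  paste(chars[shared], collapse = "")
}

#' Signed, rotation-normalized gene-order signature
#'
#' Gene names in genome order, prefixed `-` for R-strand genes, rotated
#' so the signature starts at `anchor` (default `cox1`; if absent, the
#' first record).
#'
#' @param genome An [annotated_genome()].
#' @param anchor Gene name to rotate the circular order to.
#' @return Character vector of signed gene names.
#' @export
gene_order_signature <- function(genome, anchor = "cox1") {
  sig <- vapply(genome$records, function(r)
    paste0(if (r$strand == "R") "-" else "", r$name), character(1))
  names_only <- sub("^-", "", sig)
  i <- match(anchor, names_only)
  if (is.na(i)) i <- 1L
  if (i > 1L) sig <- c(sig[i:length(sig)], sig[seq_len(i - 1L)])
  sig
}

.adjacencies <- function(sig) {
  n <- length(sig)
  paste(sig, sig[c(2:n, 1L)], sep = ">")
}

#' Compare two circular gene orders
#'
#' Two signatures are `identical` when one is a rotation of the other
#' (signs included). Otherwise the number of breakpoints is reported:
#' adjacencies (ordered signed pairs on the circle) present in `a` but
#' not in `b`.
#'
#' @param a,b Signed gene-order signatures ([gene_order_signature()])
#'   over the same gene-name alphabet.
#' @return List with `identical` (logical) and `breakpoints` (integer).
#' @export
compare_order <- function(a, b) {
  na <- sort(sub("^-", "", a)); nb <- sort(sub("^-", "", b))
  if (!identical(na, nb))
    stop("gene-name alphabets differ: ",
         paste(union(setdiff(na, nb), setdiff(nb, na)), collapse = ", "))
  rotations <- lapply(seq_along(b), function(k)
    c(b[k:length(b)], if (k > 1L) b[seq_len(k - 1L)]))
  ident <- any(vapply(rotations, identical, logical(1), y = a))
  bp <- sum(!.adjacencies(a) %in% .adjacencies(b))
  list(identical = ident, breakpoints = as.integer(bp))
}

#' The ancestral insect mitogenome gene order
#'
#' The putative ancestral arrangement differs from the derived
#' lepidopteran order only in the tRNA block downstream of the control
#' region: ancestral `trnI-trnQ-trnM` versus derived `trnM-trnI-trnQ`.
#'
#' @param genome An [annotated_genome()] in the derived order.
#' @return The genome's signature with the trnM/trnI/trnQ block restored
#'   to the ancestral order.
#' @export
ancestral_signature <- function(genome) {
  sig <- gene_order_signature(genome)
  bare <- sub("^-", "", sig)
  i <- match(c("trnM", "trnI", "trnQ"), bare)
  if (any(is.na(i)) || !all(diff(i) == 1L))
    stop("genome lacks a contiguous trnM-trnI-trnQ block")
  sig[i] <- sig[i][c(2L, 3L, 1L)]   # I, Q, M
  sig
}
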