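# Seeded generator of circular mitogenomes and aligned clades with the
# statistical structure the analyses assume: AT-rich composition with
# prescribed skews, 13 translatable PCGs with ATN/CGA starts and
# complete or incomplete-T stops, the lepidopteran trnM-trnI-trnQ gene
# order, a 7 bp ATGATAA atp8/atp6 junction, an ATACTAA spacer motif,
# and an A+T-rich region carrying ATAGA + poly-T, (AT)n and poly-A
# elements. Every planted element is returned in a truth table so the
# scanners can be tested by plant-and-recover.

# Default genome layout: the lepidopteran gene order with
# coordinate-derived lengths and gaps; PCG lengths are adjusted to the
# nearest value compatible with their stop type (complete stop: length
# % 3 == 0; incomplete T: length % 3 == 1).
.default_layout <- function() {
  L <- function(name, class, strand, len, gap, ac = NA, st = NA, sp = NA)
    data.frame(name = name, class = class, strand = strand, len = len,
               gap_after = gap, anticodon = ac, start_codon = st,
               stop_codon = sp, stringsAsFactors = FALSE)
  rbind(
    L("trnM", "tRNA", "F", 68, 0, "CAT"),
    L("trnI", "tRNA", "F", 68, -3, "GAT"),
    L("trnQ", "tRNA", "R", 69, 53, "TTG"),
    L("nad2", "PCG", "F", 1017, -2, NA, "ATT", "TAA"),
    L("trnW", "tRNA", "F", 70, -8, "TCA"),
    L("trnC", "tRNA", "R", 64, 0, "GCA"),
    L("trnY", "tRNA", "R", 64, 14, "GTA"),
    L("cox1", "PCG", "F", 1528, 0, NA, "CGA", "T"),
    L("trnL2(UUR)", "tRNA", "F", 67, 0, "TAA"),
    L("cox2", "PCG", "F", 682, 0, NA, "ATG", "T"),
    L("trnK", "tRNA", "F", 71, 1, "CTT"),
    L("trnD", "tRNA", "F", 67, 0, "GTC"),
    L("atp8", "PCG", "F", 165, -7, NA, "ATC", "TAA"),
    L("atp6", "PCG", "F", 678, -1, NA, "ATG", "TAA"),
    L("cox3", "PCG", "F", 795, 2, NA, "ATG", "TAA"),
    L("trnG", "tRNA", "F", 69, 0, "TCC"),
    L("nad3", "PCG", "F", 351, 3, NA, "ATC", "TAA"),
    L("trnA", "tRNA", "F", 66, -1, "TGC"),
    L("trnR", "tRNA", "F", 65, 0, "TCG"),
    L("trnN", "tRNA", "F", 67, -1, "GTT"),
    L("trnS1(AGN)", "tRNA", "F", 67, -1, "GCT"),
    L("trnE", "tRNA", "F", 66, -2, "TTC"),
    L("trnF", "tRNA", "R", 67, 0, "GAA"),
    L("nad5", "PCG", "R", 1723, 15, NA, "ATA", "T"),
    L("trnH", "tRNA", "R", 57, 10, "GTG"),
    L("nad4", "PCG", "R", 1387, -1, NA, "ATT", "T"),
    L("nad4L", "PCG", "R", 285, 4, NA, "ATG", "TAA"),
    L("trnT", "tRNA", "F", 65, -1, "TGT"),
    L("trnP", "tRNA", "R", 66, 1, "TGG"),
    L("nad6", "PCG", "F", 531, -1, NA, "ATG", "TAA"),
    L("cytb", "PCG", "F", 1143, -6, NA, "ATG", "TAA"),
    L("trnS2(UCN)", "tRNA", "F", 65, 18, "TGA"),
    L("nad1", "PCG", "R", 936, 0, NA, "ATG", "TAA"),
    L("trnL1(CUN)", "tRNA", "R", 67, 0, "TAG"),
    L("rrnL", "rRNA", "R", 1338, 0),
    L("trnV", "tRNA", "R", 66, 1, "TAC"),
    L("rrnS", "rRNA", "R", 779, 1),
    L("AT_rich_region", "control_region", "F", 351, 0))
}

#' Per-base probabilities from composition targets
#'
#' Closed-form inversion of (A+T fraction, AT skew, GC skew) into the
#' four base probabilities: `pA = AT (1 + at_skew) / 2`, etc.
#'
#' @param pct_AT Target A+T percentage.
#' @param at_skew,gc_skew Target skews.
#' @return Named numeric probability vector over A, C, G, T.
#' @export
composition_probs <- function(pct_AT = 80.29, at_skew = 0.017,
                              gc_skew = -0.231) {
  at <- pct_AT / 100
  p <- c(A = at * (1 + at_skew) / 2,
         C = (1 - at) * (1 - gc_skew) / 2,
         G = (1 - at) * (1 + gc_skew) / 2,
         T = at * (1 - at_skew) / 2)
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  p
}

# Codon weights proportional to the product of per-position base
# probabilities, stops removed. Dropping the (AT-rich) stop codons
# shifts the expected base composition away from the target, so the
# per-position probabilities are recalibrated by iterative
# proportional fitting until the expected composition of the sampled
# codons matches the target probabilities.
.default_codon_bias <- function(probs) {
  fam <- codon_family_table()
  stops <- fam$family == "Stop"
  letters3 <- strsplit(fam$codon, "", fixed = TRUE)
  q <- probs
  for (iter in 1:60) {
    w <- vapply(letters3, function(b) prod(q[b]), numeric(1))
    w[stops] <- 0
    w <- w / sum(w)
    e <- c(A = 0, C = 0, G = 0, T = 0)
    for (i in seq_along(w)) for (b in letters3[[i]]) e[b] <- e[b] + w[i]
    e <- e / 3
    if (max(abs(e - probs)) < 1e-9) break
    q <- q * probs / e
    q <- q / sum(q)
  }
  stats::setNames(w, fam$codon)
}

#' Specification of a synthetic mitogenome
#'
#' The defaults state the emulated world: a circular genome in the
#' lepidopteran gene order with near-published feature lengths and
#' gaps, whole-genome A+T of 80.29% with AT skew 0.017 and GC skew
#' -0.231, cox1 started by CGA and stopped by an incomplete T, a 7 bp
#' ATGATAA junction across atp8/atp6, ATACTAA inside the trnS2-nad1
#' spacer, and a control region carrying ATAGA + 17 bp poly-T, (AT)9
#' and a 12 bp poly-A.
#'
#' @param seed Integer seed; fully determines the genome.
#' @param identifier Taxon label.
#' @param pct_AT,at_skew,gc_skew Composition targets for the background
#'   and codon bias.
#' @param layout Layout data frame (see source of `.default_layout`);
#'   columns `name, class, strand, len, gap_after, anticodon,
#'   start_codon, stop_codon`.
#' @param codon_bias Optional named weights over the 64 codons (stops
#'   must be zero); default derived from the composition targets.
#' @param junction_motif Motif overwritten across the atp8/atp6
#'   overlap.
#' @param spacer_motif,spacer_motif_pair,spacer_motif_offset Motif
#'   planted inside the named spacer at the given 0-based offset.
#' @param ataga_offset,polyT_len,at_copies,polyA_len Control-region
#'   plan (relative offsets within the region).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(seed = 1L, identifier = "synthetic_mitogenome",
                        pct_AT = 80.29, at_skew = 0.017, gc_skew = -0.231,
                        layout = .default_layout(), codon_bias = NULL,
                        junction_motif = "ATGATAA",
                        spacer_motif = "ATACTAA",
                        spacer_motif_pair = c("trnS2(UCN)", "nad1"),
                        spacer_motif_offset = 6L,
                        ataga_offset = 20L, polyT_len = 17L,
                        at_copies = 9L, polyA_len = 12L) {
  probs <- composition_probs(pct_AT, at_skew, gc_skew)
  # R-strand genes are sampled on their own coding strand; using the
  # complemented probabilities there preserves the F-strand skew
  # targets after reverse complementation.
  probs_R <- stats::setNames(probs[c("T", "G", "C", "A")],
                             c("A", "C", "G", "T"))
  codon_bias_R <- NULL
  if (is.null(codon_bias)) {
    codon_bias <- .default_codon_bias(probs)
    codon_bias_R <- .default_codon_bias(probs_R)
  }
  if (is.null(codon_bias_R)) codon_bias_R <- codon_bias
  # plan consistency: lengths + gaps must tile a positive circle and
  # PCG lengths must match their stop type
  if (sum(layout$len) + sum(layout$gap_after) <= 0)
    stop("layout does not tile a positive genome length")
  for (i in which(layout$class == "PCG")) {
    need <- if (layout$stop_codon[i] %in% c("TAA", "TAG")) 0L
            else if (layout$stop_codon[i] == "T") 1L
            else if (layout$stop_codon[i] == "TA") 2L
            else stop("unsupported stop codon '", layout$stop_codon[i], "'")
    if (layout$len[i] %% 3L != need)
      stop("PCG '", layout$name[i], "' length ", layout$len[i],
           " incompatible with stop '", layout$stop_codon[i], "'")
  }
  structure(list(seed = as.integer(seed), identifier = identifier,
                 pct_AT = pct_AT, at_skew = at_skew, gc_skew = gc_skew,
                 probs = probs, layout = layout, codon_bias = codon_bias,
                 codon_bias_R = codon_bias_R,
                 junction_motif = toupper(junction_motif),
                 spacer_motif = toupper(spacer_motif),
                 spacer_motif_pair = spacer_motif_pair,
                 spacer_motif_offset = as.integer(spacer_motif_offset),
                 ataga_offset = as.integer(ataga_offset),
                 polyT_len = as.integer(polyT_len),
                 at_copies = as.integer(at_copies),
                 polyA_len = as.integer(polyA_len)),
            class = "genome_spec")
}

# sample n codons from the bias table
.sample_codons <- function(n, bias) {
  if (!n) return(character())
  sample(names(bias), n, replace = TRUE, prob = bias)
}

# Write a coding string (5'->3' on the gene strand) into the F-strand
# character vector at the record's span.
.write_coding <- function(chars, start, end, strand, coding, L) {
  pos <- .circ_positions(start, end, L)
  s <- if (strand == "R") revcomp(coding) else coding
  chars[pos] <- strsplit(s, "", fixed = TRUE)[[1]]
  chars
}

.read_coding <- function(chars, start, end, strand, L) {
  pos <- .circ_positions(start, end, L)
  s <- paste(chars[pos], collapse = "")
  if (strand == "R") revcomp(s) else s
}

# deterministic repair: remove internal stop codons from a gene,
# never touching positions in `frozen` (F-strand coordinates)
.repair_pcg <- function(chars, start, end, strand, L, frozen,
                        complete_stop = TRUE) {
  pos <- .circ_positions(start, end, L)
  for (iter in 1:50) {
    coding <- .read_coding(chars, start, end, strand, L)
    k <- nchar(coding) %/% 3L
    codons <- substring(coding, 3L * seq_len(k) - 2L, 3L * seq_len(k))
    bad <- which(codons %in% c("TAA", "TAG"))
    if (complete_stop) bad <- bad[bad < k]   # terminal stop is legitimate
    if (!length(bad)) return(chars)
    b <- bad[1]
    fixed <- FALSE
    for (off in c(1L, 2L, 3L)) {
      ci <- 3L * (b - 1L) + off       # coding-strand index
      fp <- if (strand == "F") pos[ci] else pos[length(pos) - ci + 1L]
      if (fp %in% frozen) next
      repl <- "C"                      # C never creates a stop here
      chars[fp] <- if (strand == "F") repl else "G"
      fixed <- TRUE
      break
    }
    if (!fixed) stop("cannot repair internal stop: codon fully frozen")
  }
  stop("repair did not converge")
}

# break accidental occurrences of `motif` in region [rpos] (F-strand
# position vector), sparing `frozen` positions: middle base -> C/G.
.scrub_motif <- function(chars, rpos, motif, frozen) {
  for (iter in 1:50) {
    region <- paste(chars[rpos], collapse = "")
    st <- .motif_starts(region, motif)
    st <- st[!vapply(st, function(s)
      any(rpos[s:(s + nchar(motif) - 1L)] %in% frozen), logical(1))]
    if (!length(st)) return(chars)
    mid <- rpos[st[1] + nchar(motif) %/% 2L]
    chars[mid] <- if (chars[mid] == "C") "G" else "C"
  }
  chars
}

# break runs of `base` of length >= maxlen in region, sparing frozen
.scrub_runs <- function(chars, rpos, base, maxlen, frozen) {
  region <- chars[rpos]
  r <- rle(region == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= maxlen)) {
    span <- rpos[starts[i]:ends[i]]
    if (any(span %in% frozen)) next
    chars[span[length(span) %/% 2L + 1L]] <- "C"
  }
  chars
}

# break (AT)/(TA) arrays of >= maxcopies in region, sparing frozen
.scrub_at_arrays <- function(chars, rpos, maxcopies, frozen) {
  region <- paste(chars[rpos], collapse = "")
  hits <- .perfect_repeats(region, 2L, maxcopies)
  hits <- hits[hits$unit == "AT", , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    span <- rpos[hits$start[i]:hits$end[i]]
    if (any(span %in% frozen)) next
    chars[span[length(span) %/% 2L + 1L]] <- "C"
  }
  chars
}

#' Generate a synthetic annotated mitogenome
#'
#' Deterministic for a given spec (same seed, byte-identical output).
#' Background bases are sampled from the composition-target
#' probabilities; PCGs are built codon-by-codon from the codon-bias
#' table between their assigned start and stop codons (reverse-
#' complemented onto the F strand for R-strand genes); planned motifs
#' are then overwritten and a deterministic scrub pass removes
#' accidental look-alikes of the planted elements from the scanned
#' regions, so every truth entry is recovered exactly.
#'
#' @param spec A [genome_spec()].
#' @return List with `genome` (an [annotated_genome()] with sequence)
#'   and `truth` (data frame of planted elements: `kind`, `name`,
#'   `region`, `start`, `end`, `copies`, genome coordinates).
#' @export
generate_mitogenome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  lay <- spec$layout
  n <- nrow(lay)
  starts <- integer(n); ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + lay$len[i] - 1L
    pos <- ends[i] + lay$gap_after[i] + 1L
  }
  L <- ends[n] + lay$gap_after[n]
  if (any(starts < 1L) || L < max(ends))
    stop("inconsistent layout: feature plan does not tile the circle")

  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = spec$probs[c("A", "C", "G", "T")])

  truth <- data.frame(kind = character(), name = character(),
                      region = character(), start = integer(),
                      end = integer(), copies = numeric(),
                      stringsAsFactors = FALSE)
  plant <- function(kind, name, region, start, end, copies = 1) {
    truth[nrow(truth) + 1L, ] <<- list(kind, name, region,
                                       as.integer(start), as.integer(end),
                                       copies)
  }

  # --- protein-coding genes ---------------------------------------
  for (i in which(lay$class == "PCG")) {
    ncod <- (lay$len[i] - 3L -
               nchar(lay$stop_codon[i])) %/% 3L
    body <- .sample_codons(ncod, if (lay$strand[i] == "R")
      spec$codon_bias_R else spec$codon_bias)
    coding <- paste0(lay$start_codon[i], paste(body, collapse = ""),
                     lay$stop_codon[i])
    stopifnot(nchar(coding) == lay$len[i])
    chars <- .write_coding(chars, starts[i], ends[i], lay$strand[i],
                           coding, L)
  }

  frozen <- integer()

  # --- atp8/atp6 junction motif ------------------------------------
  i8 <- match("atp8", lay$name); i6 <- match("atp6", lay$name)
  if (!is.na(i8) && !is.na(i6) && nzchar(spec$junction_motif)) {
    ov <- -lay$gap_after[i8]
    if (ov != nchar(spec$junction_motif))
      stop("junction motif length must equal the atp8/atp6 overlap (",
           ov, " bp)")
    jpos <- starts[i6]:(starts[i6] + ov - 1L)
    chars[jpos] <- strsplit(spec$junction_motif, "", fixed = TRUE)[[1]]
    frozen <- c(frozen, jpos)
    plant("overlap_motif", spec$junction_motif, "atp8/atp6",
          jpos[1], jpos[ov])
  }

  # --- spacer motif -------------------------------------------------
  iu <- match(spec$spacer_motif_pair[1], lay$name)
  if (!is.na(iu) && nzchar(spec$spacer_motif)) {
    gap <- lay$gap_after[iu]
    w <- nchar(spec$spacer_motif)
    if (gap < spec$spacer_motif_offset + w)
      stop("spacer too short for the planted motif")
    s0 <- ends[iu] + 1L + spec$spacer_motif_offset
    spos <- s0:(s0 + w - 1L)
    chars[spos] <- strsplit(spec$spacer_motif, "", fixed = TRUE)[[1]]
    frozen <- c(frozen, spos)
    plant("spacer_motif", spec$spacer_motif,
          paste0("spacer:", spec$spacer_motif_pair[1], "-",
                 spec$spacer_motif_pair[2]), spos[1], spos[w])
  }

  # --- control region ----------------------------------------------
  icr <- which(lay$class == "control_region")[1]
  cr0 <- starts[icr] - 1L   # genome offset of the region
  crlen <- lay$len[icr]
  put <- function(rel, s) {
    p <- cr0 + rel
    chars[p:(p + nchar(s) - 1L)] <<- strsplit(s, "", fixed = TRUE)[[1]]
    p:(p + nchar(s) - 1L)
  }
  # ATAGA + poly-T, guarded so the planted run is maximal
  p1 <- put(spec$ataga_offset + 1L, "ATAGA")
  p2 <- put(spec$ataga_offset + 6L, strrep("T", spec$polyT_len))
  g1 <- put(spec$ataga_offset + 6L + spec$polyT_len, "A")
  plant("motif", "ATAGA", "control_region", p1[1], p1[length(p1)])
  plant("polyT", "T", "control_region", p2[1], p2[length(p2)],
        spec$polyT_len)
  # (AT)n with C guards
  at0 <- 100L
  g2 <- put(at0 - 1L, "C")
  p3 <- put(at0, strrep("AT", spec$at_copies))
  g3 <- put(at0 + 2L * spec$at_copies, "C")
  plant("microsatellite", "AT", "control_region", p3[1], p3[length(p3)],
        spec$at_copies)
  # poly-A near the trnM-facing end, T guards
  pa0 <- crlen - spec$polyA_len - 3L
  g4 <- put(pa0 - 1L, "T")
  p4 <- put(pa0, strrep("A", spec$polyA_len))
  g5 <- put(pa0 + spec$polyA_len, "T")
  plant("polyA", "A", "control_region", p4[1], p4[length(p4)],
        spec$polyA_len)
  protect <- c(frozen, p1, p2, p3, p4)            # planted spans only
  frozen <- c(protect, g1, g2, g3, g4, g5)        # guards too, for repair

  # --- repair PCG frames around forced motifs ----------------------
  for (pass in 1:5) {
    for (i in which(lay$class == "PCG"))
      chars <- .repair_pcg(chars, starts[i], ends[i], lay$strand[i], L,
                           frozen,
                           complete_stop = lay$stop_codon[i] %in% c("TAA", "TAG"))
  }

  # --- scrub accidental look-alikes from scanned regions -----------
  crpos <- .circ_positions(starts[icr], ends[icr], L)
  chars <- .scrub_motif(chars, crpos, "ATAGA", protect)
  chars <- .scrub_runs(chars, crpos, "T", 10L, protect)
  chars <- .scrub_runs(chars, crpos, "A", 10L, protect)
  chars <- .scrub_at_arrays(chars, crpos, spec$at_copies, protect)
  for (i in seq_len(n)) {
    if (lay$gap_after[i] < 10L) next
    sp <- (ends[i] + 1L):(ends[i] + lay$gap_after[i])
    chars <- .scrub_motif(chars, sp, spec$spacer_motif, protect)
    chars <- .scrub_motif(chars, sp, spec$junction_motif, protect)
  }

  records <- lapply(seq_len(n), function(i) {
    gene_record(name = lay$name[i], feature_class = lay$class[i],
                strand = lay$strand[i], start = starts[i], end = ends[i],
                anticodon = lay$anticodon[i],
                start_codon = lay$start_codon[i],
                stop_codon = lay$stop_codon[i],
                size_printed = lay$len[i],
                intergenic_printed = lay$gap_after[i])
  })
  genome <- annotated_genome(spec$identifier, records, length = L,
                             sequence = paste(chars, collapse = ""))
  list(genome = genome, truth = truth)
}

#' Specification of a synthetic clade
#'
#' States the generating world for phylogeny tests: sequences evolved
#' site-independently down a known tree under the Kimura
#' two-parameter model (no indels, so alignment columns are preserved
#' and [build_supermatrix()] preconditions hold by construction).
#'
#' @param tree A `phylo` tree or Newick string with branch lengths
#'   (expected substitutions per site). Default: six taxa in three
#'   cherries with 0.05 internal edges.
#' @param gene_lengths Named integer vector of per-gene alignment
#'   lengths (default: 240 bp for each of the 13 PCGs).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param probs Root base probabilities (default: the AT-rich
#'   mitogenome composition).
#' @param seed Integer seed.
#' @return An object of class `clade_spec`.
#' @export
clade_spec <- function(tree = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05,(E:0.1,F:0.1):0.05);",
                       gene_lengths = stats::setNames(rep(240L, 13L), mt_pcg_names),
                       kappa = 2, probs = composition_probs(), seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("generating tree needs non-negative branch lengths")
  if (sum(gene_lengths) < 1L) stop("zero-length alignment")
  structure(list(tree = tree, gene_lengths = gene_lengths, kappa = kappa,
                 probs = probs, seed = as.integer(seed)),
            class = "clade_spec")
}

# evolve a parent character vector along a branch of length d under K2P
.k2p_evolve <- function(seq, d, kappa) {
  if (d <= 0) return(seq)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)     # per transversion target
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  u <- stats::runif(length(seq))
  out <- seq
  sel <- u < p_ts
  out[sel] <- ts_partner[seq[sel]]
  sel2 <- !sel & u < p_ts + p_tv
  out[sel2] <- tv1[seq[sel2]]
  sel3 <- !sel & !sel2 & u < p_ts + 2 * p_tv
  out[sel3] <- tv2[seq[sel3]]
  out
}

#' Generate an aligned synthetic clade
#'
#' @param spec A [clade_spec()].
#' @return List with `genomes` (list of [annotated_genome()], one per
#'   tip, carrying the 13 aligned PCGs as abutting features) and
#'   `tree` (the generating tree).
#' @export
generate_clade <- function(spec = clade_spec()) {
  stopifnot(inherits(spec, "clade_spec"))
  set.seed(spec$seed)
  tree <- spec$tree
  nt <- length(tree$tip.label)
  width <- sum(spec$gene_lengths)
  root <- nt + 1L
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[root]] <- sample(c("A", "C", "G", "T"), width, replace = TRUE,
                         prob = spec$probs[c("A", "C", "G", "T")])
  # preorder: parents are always filled before their children
  done <- rep(FALSE, nt + tree$Nnode); done[root] <- TRUE
  remaining <- seq_len(nrow(tree$edge))
  while (length(remaining)) {
    ready <- remaining[done[tree$edge[remaining, 1]]]
    if (!length(ready)) stop("disconnected tree")
    for (e in ready) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      seqs[[ch]] <- .k2p_evolve(seqs[[p]], tree$edge.length[e], spec$kappa)
      done[ch] <- TRUE
    }
    remaining <- setdiff(remaining, ready)
  }
  ends <- cumsum(spec$gene_lengths)
  starts <- ends - spec$gene_lengths + 1L
  genomes <- lapply(seq_len(nt), function(i) {
    s <- paste(seqs[[i]], collapse = "")
    records <- lapply(seq_along(spec$gene_lengths), function(g)
      gene_record(name = names(spec$gene_lengths)[g], feature_class = "PCG",
                  strand = "F", start = starts[g], end = ends[g],
                  start_codon = substring(s, starts[g], starts[g] + 2L)))
    annotated_genome(tree$tip.label[i], records, length = width,
                     sequence = s)
  })
  list(genomes = genomes, tree = tree)
}
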