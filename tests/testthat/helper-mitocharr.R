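# Shared fixtures and independent oracles for the suite.

fixture_annotation <- function() {
  system.file("extdata", "daphnis_nerii_annotation.tsv",
              package = "mitocharr")
}

fixture_genome <- function() {
  read_annotation_table(fixture_annotation(), identifier = "D_nerii")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# toy circular sequence genome with arbitrary records
toy_genome <- function(sequence, records, identifier = "toy") {
  annotated_genome(identifier, records, length = nchar(sequence),
                   sequence = sequence)
}

# ---- oracles ------------------------------------------------------

# naive per-character base counting
oracle_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  for (ch in chars) if (ch %in% names(out)) out[ch] <- out[ch] + 1L
  out
}

# longest run of `base` by substring enumeration
oracle_longest_run <- function(seq, base) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  best <- 0L; best_start <- NA_integer_
  for (i in seq_along(chars)) {
    j <- i
    while (j <= length(chars) && chars[j] == base) j <- j + 1L
    if (j - i > best) { best <- j - i; best_start <- i }
  }
  list(len = best, start = best_start)
}

# exhaustive perfect-repeat enumerator: every substring checked for
# every unit size (independent of the linear extension scan used by
# the implementation)
oracle_repeats <- function(region, unit_sizes, min_copies) {
  chars <- strsplit(toupper(region), "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_primitive <- function(unit) {
    u <- nchar(unit)
    if (u == 1L) return(TRUE)
    for (d in seq_len(u - 1L)) {
      if (u %% d == 0L &&
          strrep(substring(unit, 1L, d), u %/% d) == unit) return(FALSE)
    }
    TRUE
  }
  least_rot <- function(unit) {
    u <- nchar(unit)
    min(vapply(seq_len(u), function(k)
      paste0(substring(unit, k, u), substring(unit, 1L, k - 1L)),
      character(1)))
  }
  hits <- list()
  for (u in sort(unique(as.integer(unit_sizes)))) {
    if (u > n) next
    for (i in seq_len(n - u + 1L)) for (j in (i + u - 1L):n) {
      len <- j - i + 1L
      if (len / u < min_copies) next
      ok <- len == u || all(chars[(i + u):j] == chars[(i + u):j - u])
      if (!ok) next
      # maximality
      if (i > 1L && chars[i - 1L] == chars[i - 1L + u]) next
      if (j < n && chars[j + 1L] == chars[j + 1L - u]) next
      unit <- paste(chars[i:(i + u - 1L)], collapse = "")
      if (!is_primitive(unit)) next
      hits[[length(hits) + 1L]] <- data.frame(
        unit = least_rot(unit), unit_size = u, copies = len / u,
        start = i, end = j, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(unit = character(), unit_size = integer(),
                      copies = numeric(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start, out$unit_size), ]
  rownames(out) <- NULL
  out
}

# additive distance matrix from a random tree (patristic distances)
oracle_additive_matrix <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# check that every planted truth entry is recovered by the matching
# scanner at its exact genome coordinates
check_plant_and_recover <- function(gen) {
  g <- gen$genome
  truth <- gen$truth
  hits <- spacer_motif_report(g, ms_min_copies = 5)
  ok <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    ok[i] <- switch(tr$kind,
      overlap_motif = identical(motif_at_overlap(g, c("atp8", "atp6")),
                                tr$name),
      spacer_motif = any(hits$kind == "motif" & hits$motif == tr$name &
                           hits$start == tr$start & hits$end == tr$end &
                           hits$region == tr$region),
      motif = any(hits$kind == "motif" & hits$motif == tr$name &
                    hits$start == tr$start & hits$end == tr$end),
      polyT = any(hits$kind == "polyT" & hits$start == tr$start &
                    hits$end == tr$end & hits$copies == tr$copies),
      microsatellite = any(hits$kind == "microsatellite" &
                             hits$motif == tr$name &
                             hits$start == tr$start & hits$end == tr$end &
                             hits$copies == tr$copies),
      polyA = any(hits$kind == "polyA" & hits$start == tr$start &
                    hits$end == tr$end & hits$copies == tr$copies),
      FALSE)
  }
  stats::setNames(ok, paste(truth$kind, truth$name))
}
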