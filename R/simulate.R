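#' Seeded synthetic-data generators
#'
#' Deterministic generators for every fixture the toolkit's tests need: toy
#' references, two-haplotype paired-end fragment sets for phasing,
#' deletion-bearing sequences with planted microhomology, and per-amplicon
#' read sets for depth QC. Reads are emitted as already-aligned records
#' (their coordinates are known by construction), so no external aligner is
#' required; [write_fastq()] exists for users who want to run one anyway.
#' Identical seed and scenario give identical output.
#'
#' @name lr-simulate
NULL

# Run code under a temporary RNG state so generators are seeded and
# side-effect free.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation scenario defaults
#'
#' Read geometry defaults mirror the sequencing protocol the toolkit
#' supports: 2 x 151 bp paired-end reads from ~350-400 bp insert libraries
#' (modelled as 375 +/- 25 bp).
#'
#' @param read_length Read length in bp (default 151).
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp.
#' @param depth Target fold-coverage (default 50).
#' @param error_rate Per-base substitution error probability (default 0;
#'   the error model is substitution-only so phasing and breakpoint truth
#'   stay unambiguous).
#' @return Named list of scenario parameters.
#' @export
sim_scenario <- function(read_length = 151L, insert_mean = 375, insert_sd = 25,
                         depth = 50, error_rate = 0) {
  list(read_length = as.integer(read_length), insert_mean = insert_mean,
    insert_sd = insert_sd, depth = depth, error_rate = error_rate)
}

#' Random toy reference sequence
#'
#' Uniform-random A/C/G/T sequence, reproducible by seed.
#'
#' @param length Sequence length in bp (> 0).
#' @param seed Integer seed.
#' @return Character sequence of the requested length.
#' @export
make_reference <- function(length, seed) {
  if (length <= 0) rlang::abort("reference length must be > 0")
  with_local_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}

#' Plant a deletion with controlled microhomology
#'
#' Constructs the scenario of sequencing a junction-spanning amplicon over
#' a known deletion: rewrites the 3' flank of the (mutated) reference so
#' its first `mh_len` bases repeat the first `mh_len` bases of the deleted
#' segment, then deletes the segment to produce the observed sequence. With
#' `exact = TRUE` (default) the bases bordering the planted repeat are
#' adjusted so no accidental flank identity extends the microhomology, and
#' the truth placement set is exactly `mh_len + 1` positions.
#'
#' @param reference Character reference sequence.
#' @param start 1-based first deleted position.
#' @param length Deletion length in bp.
#' @param mh_len Planted microhomology length (must be < `length` when
#'   `exact`).
#' @param exact Block accidental microhomology extension (default TRUE).
#' @return List with `reference` (the mutated reference carrying the
#'   planted repeat), `observed` (the deleted sequence), and `truth`
#'   (tibble `five_start`, `five_end`, `three_start`, `three_end`,
#'   `deletion_length`, `microhomology_len`).
#' @export
plant_deletion <- function(reference, start, length, mh_len, exact = TRUE) {
  n <- nchar(reference)
  if (start < 1 || length < 1 || mh_len < 0) {
    rlang::abort("start/length must be >= 1 and mh_len >= 0")
  }
  if (start + length - 1L + mh_len > n) {
    rlang::abort("deletion plus microhomology flank exceeds the reference")
  }
  if (exact && mh_len >= length) {
    rlang::abort("exact planting requires mh_len < deletion length")
  }
  mut <- reference
  if (mh_len > 0L) {
    substr(mut, start + length, start + length + mh_len - 1L) <-
      substr(mut, start, start + mh_len - 1L)
  }
  other_base <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[1]
  if (exact) {
    # block right extension: base after the planted repeat inside the
    # deleted segment must differ from the base after it in the 3' flank
    q_del <- start + mh_len
    q_flank <- start + length + mh_len
    if (q_flank <= n && substr(mut, q_del, q_del) == substr(mut, q_flank, q_flank)) {
      avoid <- substr(mut, q_flank, q_flank)
      if (start > 1L && q_del == start + length - 1L) {
        avoid <- c(avoid, substr(mut, start - 1L, start - 1L))
      }
      substr(mut, q_del, q_del) <- other_base(avoid)
    }
    # block left extension: last deleted base must differ from the base
    # just before the deletion
    if (start > 1L) {
      p_del <- start + length - 1L
      avoid <- substr(mut, start - 1L, start - 1L)
      if (p_del == start + mh_len && q_flank <= n) {
        avoid <- c(avoid, substr(mut, q_flank, q_flank))
      }
      if (substr(mut, p_del, p_del) == avoid[1]) {
        substr(mut, p_del, p_del) <- other_base(avoid)
      }
    }
  }
  observed <- paste0(substr(mut, 1L, start - 1L), substr(mut, start + length, n))
  if (exact) {
    truth <- tibble::tibble(
      five_start = start, five_end = start + mh_len,
      three_start = start + length - 1L, three_end = start + length - 1L + mh_len,
      deletion_length = length, microhomology_len = mh_len
    )
  } else {
    p <- lcp_len(mut, observed)
    s <- lcs_len(mut, observed)
    mh <- p + s - nchar(observed)
    ls <- nchar(observed) - s + 1L
    truth <- tibble::tibble(
      five_start = ls, five_end = p + 1L,
      three_start = ls + length - 1L, three_end = p + length,
      deletion_length = length, microhomology_len = mh
    )
  }
  list(reference = mut, observed = observed, truth = truth)
}

# Apply one haplotype's variants to a reference. Returns the haplotype
# sequence plus an alignment-op table mapping haplotype to reference
# coordinates (M consumes both, D reference only, I haplotype only; D rows
# store hap_before = last haplotype base preceding the deleted stretch).
apply_variants <- function(reference, variants) {
  v <- tibble::as_tibble(variants)
  n <- nchar(reference)
  ops <- list()
  pieces <- list()
  cur_ref <- 1L
  cur_hap <- 1L
  if (nrow(v) > 0L) {
    v <- dplyr::arrange(v, .data$pos)
    if (any(v$pos < 1L | v$pos + nchar(v$ref) - 1L > n)) {
      rlang::abort("variant outside reference")
    }
    if (nrow(v) > 1L && any(v$pos[-1] <= v$pos[-nrow(v)] + nchar(v$ref[-nrow(v)]) - 1L)) {
      rlang::abort("overlapping variants on one haplotype")
    }
    for (i in seq_len(nrow(v))) {
      ref_a <- v$ref[i]
      alt_a <- v$alt[i]
      type <- classify_site(ref_a, alt_a)
      if (is.null(type)) {
        rlang::abort(sprintf("unsupported REF/ALT pair %s>%s at %d", ref_a, alt_a, v$pos[i]))
      }
      if (substr(reference, v$pos[i], v$pos[i] + nchar(ref_a) - 1L) != ref_a) {
        rlang::abort(sprintf("REF mismatch at %d", v$pos[i]))
      }
      # leading match block up to and including the anchored/substituted part
      pre_len <- v$pos[i] - cur_ref
      lead_hap <- if (type == "del") substr(alt_a, 1L, nchar(alt_a)) else alt_a
      m_len <- pre_len + (if (type == "sub") nchar(alt_a)
                          else if (type == "del") nchar(alt_a)
                          else nchar(ref_a))
      pieces[[length(pieces) + 1L]] <- paste0(
        substr(reference, cur_ref, v$pos[i] - 1L),
        if (type == "ins") ref_a else lead_hap)
      ops[[length(ops) + 1L]] <- list(op = "M", len = m_len,
        ref_start = cur_ref, hap_start = cur_hap)
      cur_ref <- cur_ref + m_len
      cur_hap <- cur_hap + m_len
      if (type == "del") {
        d_len <- nchar(ref_a) - nchar(alt_a)
        ops[[length(ops) + 1L]] <- list(op = "D", len = d_len,
          ref_start = cur_ref, hap_start = cur_hap - 1L)
        cur_ref <- cur_ref + d_len
      } else if (type == "ins") {
        i_len <- nchar(alt_a) - nchar(ref_a)
        pieces[[length(pieces) + 1L]] <- substr(alt_a, nchar(ref_a) + 1L, nchar(alt_a))
        ops[[length(ops) + 1L]] <- list(op = "I", len = i_len,
          ref_start = cur_ref, hap_start = cur_hap)
        cur_hap <- cur_hap + i_len
      }
    }
  }
  if (cur_ref <= n) {
    pieces[[length(pieces) + 1L]] <- substr(reference, cur_ref, n)
    ops[[length(ops) + 1L]] <- list(op = "M", len = n - cur_ref + 1L,
      ref_start = cur_ref, hap_start = cur_hap)
  }
  ops <- dplyr::bind_rows(ops)
  list(seq = paste(unlist(pieces), collapse = ""), ops = ops)
}

# Alignment position + CIGAR for a read covering haplotype coordinates
# [hs, he]. Leading/trailing insertions become soft clips; deletions at the
# read boundary are dropped.
hap_read_record <- function(ops, hs, he) {
  out_op <- character(0)
  out_len <- integer(0)
  out_ref <- integer(0) # ref start per emitted op (NA for I/S)
  for (k in seq_len(nrow(ops))) {
    o <- ops[k, ]
    if (o$op == "D") {
      if (o$hap_start >= hs && o$hap_start < he) {
        out_op <- c(out_op, "D")
        out_len <- c(out_len, o$len)
        out_ref <- c(out_ref, o$ref_start)
      }
    } else {
      h0 <- max(hs, o$hap_start)
      h1 <- min(he, o$hap_start + o$len - 1L)
      if (h0 > h1) next
      if (o$op == "M") {
        out_op <- c(out_op, "M")
        out_len <- c(out_len, h1 - h0 + 1L)
        out_ref <- c(out_ref, o$ref_start + (h0 - o$hap_start))
      } else { # I
        out_op <- c(out_op, "I")
        out_len <- c(out_len, h1 - h0 + 1L)
        out_ref <- c(out_ref, NA_integer_)
      }
    }
  }
  # trim boundary artefacts
  while (length(out_op) && out_op[1] == "D") {
    out_op <- out_op[-1]; out_len <- out_len[-1]; out_ref <- out_ref[-1]
  }
  while (length(out_op) && out_op[length(out_op)] == "D") {
    n <- length(out_op)
    out_op <- out_op[-n]; out_len <- out_len[-n]; out_ref <- out_ref[-n]
  }
  if (length(out_op) && out_op[1] == "I") out_op[1] <- "S"
  if (length(out_op) && out_op[length(out_op)] == "I") out_op[length(out_op)] <- "S"
  if (!any(out_op == "M")) {
    return(NULL) # read lies entirely within an insertion
  }
  first_m <- which(out_op == "M")[1]
  # merge adjacent runs of the same op
  keep_op <- character(0)
  keep_len <- integer(0)
  for (k in seq_along(out_op)) {
    if (length(keep_op) && keep_op[length(keep_op)] == out_op[k]) {
      keep_len[length(keep_len)] <- keep_len[length(keep_len)] + out_len[k]
    } else {
      keep_op <- c(keep_op, out_op[k])
      keep_len <- c(keep_len, out_len[k])
    }
  }
  list(pos = out_ref[first_m],
    cigar = paste0(keep_len, keep_op, collapse = ""))
}

add_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < error_rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
    character(1))
  paste(ch, collapse = "")
}

#' Simulate paired-end fragments from two haplotypes
#'
#' Samples sequencing fragments equally from two haplotypes of a reference
#' (each haplotype defined by its variant list), emits both mates as
#' aligned records with correct positions and CIGARs, and records each
#' fragment's source haplotype as phasing ground truth. Substitution
#' errors are applied per base at `scenario$error_rate`.
#'
#' @param reference Character reference sequence.
#' @param haplotype_variants Tibble with columns `hap` (1 or 2), `pos`,
#'   `ref`, `alt`; zero rows for a variant-free simulation.
#' @param scenario Scenario list from [sim_scenario()].
#' @param seed Integer seed.
#' @param contig Reference name used in the alignment records.
#' @param prefix Fragment-name prefix.
#' @return List with `alignments` (tibble, two records per fragment),
#'   `truth` (tibble `fragment_id`, `haplotype`), and `haplotypes`
#'   (list of the two haplotype sequences).
#' @export
simulate_fragments <- function(reference, haplotype_variants,
                               scenario = sim_scenario(), seed = 1L,
                               contig = "ref", prefix = "frag") {
  v <- tibble::as_tibble(haplotype_variants)
  if (nrow(v) > 0L && !"hap" %in% names(v)) {
    rlang::abort("haplotype_variants needs a 'hap' column (1 or 2)")
  }
  h1 <- apply_variants(reference, v[v$hap == 1, c("pos", "ref", "alt"), drop = FALSE])
  h2 <- apply_variants(reference, v[v$hap == 2, c("pos", "ref", "alt"), drop = FALSE])
  haps <- list(h1, h2)
  rl <- scenario$read_length
  n_frag <- round(scenario$depth * nchar(reference) / (2 * rl))
  if (n_frag <= 0) {
    return(list(alignments = empty_alignments(),
      truth = tibble::tibble(fragment_id = character(), haplotype = integer()),
      haplotypes = lapply(haps, `[[`, "seq")))
  }
  with_local_seed(seed, {
    hap_of <- sample(1:2, n_frag, replace = TRUE)
    recs <- vector("list", 2L * n_frag)
    for (f in seq_len(n_frag)) {
      hp <- haps[[hap_of[f]]]
      hlen <- nchar(hp$seq)
      flen <- as.integer(round(stats::rnorm(1, scenario$insert_mean, scenario$insert_sd)))
      flen <- max(rl, min(flen, hlen))
      s <- sample.int(hlen - flen + 1L, 1L)
      e <- s + flen - 1L
      qname <- sprintf("%s%05d", prefix, f)
      spans <- list(c(s, min(s + rl - 1L, e)), c(max(e - rl + 1L, s), e))
      flags <- c(99L, 147L)
      for (m in 1:2) {
        rec <- hap_read_record(hp$ops, spans[[m]][1], spans[[m]][2])
        if (is.null(rec)) next
        sq <- add_errors(substr(hp$seq, spans[[m]][1], spans[[m]][2]),
          scenario$error_rate)
        recs[[2L * (f - 1L) + m]] <- tibble::tibble(
          qname = qname, flag = flags[m], rname = contig, pos = rec$pos,
          mapq = 60L, cigar = rec$cigar, seq = sq,
          qual = strrep("I", nchar(sq)))
      }
    }
    aln <- dplyr::bind_rows(recs)
    list(
      alignments = aln,
      truth = tibble::tibble(fragment_id = sprintf("%s%05d", prefix, seq_len(n_frag)),
        haplotype = hap_of),
      haplotypes = lapply(haps, `[[`, "seq")
    )
  })
}

#' Simulate reads from every amplicon of a panel
#'
#' Generates reads per amplicon independently at the scenario depth, so
#' regions where amplicons overlap receive the summed depth — the coverage
#' step that reveals amplicon overlaps in real panel data. `placement =
#' "random"` draws paired fragments uniformly within each amplicon;
#' `placement = "tiled"` lays down deterministic non-overlapping
#' single-end tilings so that every base of an amplicon gets exactly
#' `depth` aligned bases (noiseless mode: overlap depth is exactly the sum).
#'
#' @param panel An `lr_panel`.
#' @param reference Named character vector or list: contig -> sequence.
#' @param scenario Scenario list from [sim_scenario()].
#' @param seed Integer seed.
#' @param placement `"random"` or `"tiled"`.
#' @return Alignment tibble.
#' @export
simulate_amplicon_pool <- function(panel, reference, scenario = sim_scenario(),
                                   seed = 1L, placement = c("random", "tiled")) {
  placement <- match.arg(placement)
  if (nrow(panel) == 0L) {
    return(empty_alignments())
  }
  rl <- scenario$read_length
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    amp <- panel[i, ]
    refseq <- reference[[amp$contig]]
    if (is.null(refseq)) rlang::abort(sprintf("no reference sequence for contig %s", amp$contig))
    sub <- substr(refseq, amp$start, amp$end)
    if (placement == "tiled") {
      starts <- seq(1L, nchar(sub), by = rl)
      lens <- pmin(rl, nchar(sub) - starts + 1L)
      reps <- max(1L, as.integer(round(scenario$depth)))
      tile <- tibble::tibble(
        qname = sprintf("%s_t%02d_%04d", amp$amplicon,
          rep(seq_len(reps), each = length(starts)), rep(seq_along(starts), reps)),
        flag = 0L, rname = amp$contig,
        pos = amp$start + rep(starts, reps) - 1L,
        mapq = 60L,
        cigar = sprintf("%dM", rep(lens, reps)),
        seq = vapply(rep(seq_along(starts), reps), function(k) {
          add_errors(substr(sub, starts[k], starts[k] + lens[k] - 1L), scenario$error_rate)
        }, character(1)),
        qual = strrep("I", rep(lens, reps))
      )
      out[[i]] <- tile
    } else {
      sim <- simulate_fragments(sub, tibble::tibble(hap = integer(), pos = integer(),
        ref = character(), alt = character()),
        scenario = scenario, seed = seed + i, contig = amp$contig,
        prefix = paste0(amp$amplicon, "_f"))
      aln <- sim$alignments
      aln$pos <- aln$pos + amp$start - 1L
      out[[i]] <- aln
    }
  }
  dplyr::bind_rows(out)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Export simulated reads as FASTQ
#'
#' @param alignments Alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(alignments, path) {
  mate <- ifelse(bitwAnd(alignments$flag, 128L) > 0L, "/2", "/1")
  lines <- as.vector(rbind(
    paste0("@", alignments$qname, mate),
    alignments$seq,
    "+",
    alignments$qual))
  writeLines(lines, path)
  invisible(path)
}
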