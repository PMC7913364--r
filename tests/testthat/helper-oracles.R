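# Independent oracles used by the property tests. These deliberately use
# naive per-base / exhaustive algorithms, not the package's interval or
# string machinery.

# Per-base boolean-scan oracle for union / gap / overlap computations on a
# set of amplicon intervals within a target [tstart, tend].
scan_oracle <- function(tstart, tend, amp_starts, amp_ends) {
  pos <- tstart:tend
  depth <- integer(length(pos))
  for (k in seq_along(amp_starts)) {
    hit <- pos >= amp_starts[k] & pos <= amp_ends[k]
    depth[hit] <- depth[hit] + 1L
  }
  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start = pos[starts[keep]], end = pos[ends[keep]])
  }
  list(
    union_size = sum(depth > 0L),
    gaps = runs_of(depth == 0L),
    overlaps = runs_of(depth >= 2L)
  )
}

# Exhaustive removal-and-compare oracle: every start position s such that
# deleting L bases of ref at s yields obs.
placement_set_oracle <- function(ref, obs) {
  L <- nchar(ref) - nchar(obs)
  stopifnot(L > 0)
  out <- integer(0)
  for (s in seq_len(nchar(ref) - L + 1L)) {
    cand <- paste0(substr(ref, 1L, s - 1L), substr(ref, s + L, nchar(ref)))
    if (cand == obs) out <- c(out, s)
  }
  out
}

# Brute-force minimum-error-correction phasing oracle. frag_mat is an
# m x n matrix over {1 = ALT, 0 = REF, NA = unobserved}. Enumerates all
# 2^(n-1) haplotype bipartitions (site 1 fixed to 0) and returns every
# minimum-cost assignment.
mec_oracle <- function(frag_mat) {
  n <- ncol(frag_mat)
  grid <- as.matrix(expand.grid(rep(list(0:1), n - 1L)))
  X <- cbind(0L, grid)
  O <- !is.na(frag_mat)
  F0 <- frag_mat
  F0[!O] <- 0L
  d <- (O * F0) %*% t(1 - X) + (O * (1 - F0)) %*% t(X)
  nobs <- rowSums(O)
  cost <- colSums(pmin(d, nobs - d))
  list(assignments = X[cost == min(cost), , drop = FALSE], cost = min(cost))
}

# Relative phase of sites a and b under the oracle: "cis"/"trans" if all
# minimum-cost assignments agree, "ambiguous" otherwise.
mec_pair_call <- function(oracle, a, b) {
  par <- (oracle$assignments[, a] + oracle$assignments[, b]) %% 2L
  if (all(par == 1L)) "trans" else if (all(par == 0L)) "cis" else "ambiguous"
}

# Random error-free two-haplotype phasing instance.
random_phase_instance <- function(n_sites, n_frags) {
  hap1 <- sample(0:1, n_sites, replace = TRUE)
  frags <- matrix(NA_integer_, n_frags, n_sites)
  for (f in seq_len(n_frags)) {
    k <- sample(2:min(4L, n_sites), 1L)
    sites <- sort(sample.int(n_sites, k))
    h <- sample(1:2, 1L)
    frags[f, sites] <- if (h == 1L) hap1[sites] else 1L - hap1[sites]
  }
  list(hap1 = hap1, frags = frags)
}

# Fragment matrix -> observation tibble consumed by build_phase_graph().
frag_mat_to_obs <- function(frag_mat) {
  idx <- which(!is.na(frag_mat), arr.ind = TRUE)
  obs <- tibble::tibble(
    fragment_id = sprintf("f%04d", idx[, 1]),
    site_id = as.integer(idx[, 2]),
    allele = ifelse(frag_mat[idx] == 1L, "ALT", "REF")
  )
  obs <- obs[order(obs$fragment_id, obs$site_id), ]
  keep <- names(which(table(obs$fragment_id) >= 2L))
  obs[obs$fragment_id %in% keep, ]
}

# Tiny three-amplicon test panel used across files.
toy_panel <- function() {
  as_panel(tibble::tibble(
    locus = c("LOC_A", "LOC_A", "LOC_B"),
    amplicon = c("A_1", "A_2", "B_1"),
    contig = c("c1", "c1", "c2"),
    start = c(1L, 151L, 1L),
    end = c(200L, 400L, 120L)
  ))
}

# Minimal VCF writer for fixtures built in code.
write_test_vcf <- function(path, contig, pos, ref, alt, gt, contig_len = 10000L) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", unique(contig), contig_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s", contig, pos, ref, alt, gt)
  writeLines(c(hdr, body), path)
  path
}
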