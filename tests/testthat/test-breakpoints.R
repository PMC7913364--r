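test_that("deletion length algebra is inclusive", {
  expect_equal(deletion_length(2716981, 2787016), 70036L)
  expect_equal(deletion_length(18675498, 18676502), 1005L)
  expect_equal(deletion_length(5, 5), 1L)
  expect_error(deletion_length(10, 9), "end < start")
})

test_that("microhomology interval arithmetic matches printed coordinate pairs", {
  expect_equal(microhomology_from_intervals("94507690-94507699", "94511701-94511710"), 10L)
  expect_equal(microhomology_from_intervals("5-5", "9-9"), 1L)
  expect_equal(microhomology_from_intervals("1-4", "11-14"), 4L)
  expect_error(microhomology_from_intervals("1-4", "11-12"), "unequal")
})

test_that("infer_deletion recovers the worked microhomology example", {
  call <- infer_deletion("AAAACCTGGGGCCTTTTT", "AAAACCTTTTT", contig = "toy")
  expect_equal(call$deletion_length, 7L)
  expect_equal(call$microhomology_len, 3L)
  expect_equal(call$microhomology_seq, "CCT")
  expect_equal(c(call$five_start, call$five_end), c(5L, 8L))
  expect_equal(c(call$three_start, call$three_end), c(11L, 14L))
  expect_equal(call$hgvs, "toy:g.(5_8)_(11_14)del")
  expect_equal(placement_set_oracle("AAAACCTGGGGCCTTTTT", "AAAACCTTTTT"), 5:8)

  # unique placement, no shared flank
  u <- infer_deletion("AACCGGTT", "AATT", contig = "toy")
  expect_equal(u$deletion_length, 4L)
  expect_equal(u$microhomology_len, 0L)
  expect_equal(u$hgvs, "toy:g.3_6del")

  # error paths
  expect_error(infer_deletion("AAAA", "AAAAAA"), "not shorter")
  expect_error(infer_deletion("AACCAACC", "AGCC"), "not a clean deletion")
})

test_that("placement sets equal the exhaustive removal-and-compare oracle", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(60:2000, 1)
    refseq <- make_reference(n, 1000 + i)
    L <- sample(5:min(400, n - 30), 1)
    mh <- sample(0:min(10, L - 1), 1)
    start <- sample(10:(n - L - mh - 5), 1)
    pd <- plant_deletion(refseq, start, L, mh, exact = FALSE)
    call <- infer_deletion(pd$reference, pd$observed)
    expect_equal(seq(call$five_start, call$five_end),
      placement_set_oracle(pd$reference, pd$observed))
    expect_equal(call$deletion_length, L)
    # equivalent placements all delete the same number of bases
    expect_equal(call$three_end - call$five_end, L - 1L)
    expect_equal(call$three_start - call$five_start, L - 1L)
  }
})

test_that("N bases never extend a microhomology", {
  # without the N, flanks share "CT"; the N must block extension
  refseq <- "AAGCTNGGGGCTTTAA"
  obs <- paste0(substr(refseq, 1, 5), substr(refseq, 11, 16))
  call <- infer_deletion(refseq, obs)
  oracle <- placement_set_oracle(refseq, obs)
  expect_true(all(seq(call$five_start, call$five_end) %in% oracle))
  expect_equal(call$microhomology_len + 1L,
    call$five_end - call$five_start + 1L)
})

test_that("HGVS rendering covers exact, shifted and ambiguous forms", {
  exact <- infer_deletion("AACCGGTT", "AATT", contig = "NC_1")
  expect_equal(format_hgvs(exact), "NC_1:g.3_6del")
  amb <- infer_deletion("AAAACCTGGGGCCTTTTT", "AAAACCTTTTT", contig = "toy")
  expect_equal(format_hgvs(amb, mode = "shifted"), "toy:g.8_14del")
  # shifted and leftmost placements delete the same number of bases
  expect_equal(14 - 8 + 1, amb$deletion_length)

  # offset maps a toy sub-reference into genomic coordinates
  off <- infer_deletion("AACCGGTT", "AATT", contig = "NC_1", offset = 1001L)
  expect_equal(off$hgvs, "NC_1:g.1003_1006del")

  # single-base deletion renders without an interval
  one <- infer_deletion("ACGT", "AGT", contig = "c")
  expect_equal(one$hgvs, "c:g.2del")

  # ambiguous round trip
  p <- parse_hgvs_del(amb$hgvs)
  expect_equal(c(p$five_start, p$five_end, p$three_start, p$three_end),
    c(amb$five_start, amb$five_end, amb$three_start, amb$three_end))
  p2 <- parse_hgvs_del("NC_1:g.1003_1006del")
  expect_equal(c(p2$five_start, p2$three_start), c(1003L, 1006L))
})

test_that("planted deletions are recovered exactly across the parameter grid", {
  set.seed(31)
  ok <- 0L
  for (i in 1:40) {
    L <- sample(50:5000, 1)
    mh <- sample(0:12, 1)
    n <- L + sample(1500:2500, 1)
    refseq <- make_reference(n, 4000 + i)
    start <- sample(100:(n - L - mh - 100), 1)
    pd <- plant_deletion(refseq, start, L, mh)
    call <- infer_deletion(pd$reference, pd$observed)
    ok <- ok + (call$deletion_length == pd$truth$deletion_length &&
                call$microhomology_len == pd$truth$microhomology_len &&
                call$five_start == pd$truth$five_start &&
                call$three_end == pd$truth$three_end)
  }
  expect_equal(ok, 40L)
})

test_that("a large planted deletion with 3 bp microhomology is recovered at scale", {
  refseq <- make_reference(80000, 99)
  pd <- plant_deletion(refseq, start = 4000, length = 70036, mh_len = 3)
  call <- infer_deletion(pd$reference, pd$observed, contig = "sim9")
  expect_equal(call$deletion_length, 70036L)
  expect_equal(call$microhomology_len, 3L)
  expect_equal(deletion_length(call$five_start, call$three_start), 70036L)
})

test_that("flanking repeats are labelled by side", {
  call <- infer_deletion("AAAACCTGGGGCCTTTTT", "AAAACCTTTTT", contig = "toy")
  reps <- tibble::tibble(
    contig = c("toy", "toy", "toy", "other"),
    start = c(1L, 9L, 15L, 1L),
    end = c(4L, 10L, 18L, 4L),
    family = c("AluY", "MIR", "AluSx", "AluY"))
  ann <- annotate_flanking_repeats(call, reps, window = 50L)
  expect_equal(ann$family, c("AluY", "MIR", "AluSx"))
  expect_equal(ann$side, c("5prime", "internal", "3prime"))
  expect_equal(nrow(annotate_flanking_repeats(call, reps[0, ])), 0L)
})

test_that("deletion calls export tidy, glance and VCF-style views", {
  call <- infer_deletion("AAAACCTGGGGCCTTTTT", "AAAACCTTTTT", contig = "toy")
  expect_s3_class(tidy(call), "tbl_df")
  g <- glance(call)
  expect_equal(g$n_placements, 4L)
  rec <- deletion_vcf_record(call)
  expect_equal(rec$ALT, "<DEL>")
  expect_match(rec$INFO, "SVLEN=-7")
  expect_match(rec$INFO, "HOMLEN=3")
  expect_match(rec$INFO, "HOMSEQ=CCT")
})

test_that("consensus over junction-spanning reads feeds breakpoint inference", {
  refseq <- make_reference(3000, 55)
  pd <- plant_deletion(refseq, start = 1200, length = 600, mh_len = 2)
  # simulate reads from the deleted (observed) molecule, aligned to its own
  # coordinates, and rebuild the observed sequence by majority consensus
  sim <- simulate_fragments(pd$observed, tibble::tibble(hap = integer(),
    pos = integer(), ref = character(), alt = character()),
    sim_scenario(depth = 40), seed = 5, contig = "obs")
  len <- nchar(pd$observed)
  cons <- consensus_sequence(sim$alignments, sprintf("obs:1-%d", len))
  # interior of the consensus (read-length edge effects excluded) against
  # the matching interior of the reference
  cons_int <- substr(cons, 201, len - 200)
  ref_int <- substr(pd$reference, 201, nchar(pd$reference) - 200)
  expect_false(grepl("N", cons_int))
  call <- infer_deletion(ref_int, cons_int, contig = "sim", offset = 201L)
  expect_equal(call$deletion_length, 600L)
  expect_equal(call$microhomology_len, 2L)
})
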