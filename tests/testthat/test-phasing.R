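test_that("informative-site extraction keeps heterozygous calls and validates candidates", {
  v <- tibble::tibble(
    contig = "c", pos = c(100L, 150L, 200L, 250L, 300L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "T"),
    gt = c("0/1", "1/1", "0/1", "1/1", "0/1"))
  s <- extract_informative_sites(v, "c:1-1000")
  expect_equal(nrow(s), 3L)
  expect_equal(s$pos, c(100L, 200L, 300L))
  expect_equal(s$site_id, 1:3)

  expect_equal(nrow(extract_informative_sites(v[0, ], "c:1-1000")), 0L)

  # candidate that is homozygous in the VCF: phasing is ill-posed
  expect_error(extract_informative_sites(v, "c:1-1000",
    candidates = c("c:100:A:G", "c:150:C:T")), "not heterozygous")
  expect_error(extract_informative_sites(v, "c:1-1000",
    candidates = c("c:100:A:G", "c:999:A:T")), "not found")
  s2 <- extract_informative_sites(v, "c:1-1000",
    candidates = c("c:100:A:G", "c:300:A:T"))
  expect_equal(s2$site_id[s2$is_candidate], c(1L, 3L))
})

test_that("VCF round trip yields decomposed heterozygous records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, contig = "c",
    pos = c(100L, 150L, 200L),
    ref = c("A", "C", "G"),
    alt = c("G", "T,A", "GA"),
    gt = c("0/1", "0/2", "1/1"))
  v <- read_variants(f)
  expect_equal(v$pos, c(100L, 150L, 200L))
  expect_equal(v$alt, c("G", "A", "GA"))
  expect_equal(v$is_het, c(TRUE, TRUE, FALSE))
})

test_that("fragment observations honour quality thresholds and mate merging", {
  sites <- tibble::tibble(site_id = 1:2, contig = "c", pos = c(10L, 60L),
    ref = c("A", "G"), alt = c("T", "C"))
  mkread <- function(qname, pos, seq, qual = strrep("I", nchar(seq)), mapq = 60L,
                     flag = 0L) {
    tibble::tibble(qname = qname, flag = flag, rname = "c", pos = pos,
      mapq = mapq, cigar = paste0(nchar(seq), "M"), seq = seq, qual = qual)
  }
  base_at <- function(p, len, b, fill = "A") {
    s <- strrep(fill, len)
    substr(s, p, p) <- b
    s
  }
  # mate1 covers site1 = ALT, mate2 covers site2 = ALT -> one cis-voting fragment
  aln <- dplyr::bind_rows(
    mkread("fr1", 1L, base_at(10, 30, "T")),
    mkread("fr1", 41L, base_at(20, 30, "C", fill = "G")))
  obs <- collect_fragment_observations(aln, sites)
  expect_equal(nrow(obs), 2L)
  expect_equal(sort(obs$allele), c("ALT", "ALT"))

  # read covering only one site is uninformative
  obs1 <- collect_fragment_observations(mkread("solo", 1L, base_at(10, 30, "T")), sites)
  expect_equal(nrow(obs1), 0L)

  # low base quality at site2 blanks it, leaving one site -> dropped
  lowq <- strrep("I", 30)
  substr(lowq, 20, 20) <- "#"
  aln2 <- dplyr::bind_rows(
    mkread("fr2", 1L, base_at(10, 30, "T")),
    mkread("fr2", 41L, base_at(20, 30, "C", fill = "G"), qual = lowq))
  expect_equal(nrow(collect_fragment_observations(aln2, sites)), 0L)

  # low mapping quality discards the whole read
  aln3 <- dplyr::bind_rows(
    mkread("fr3", 1L, base_at(10, 30, "T"), mapq = 5L),
    mkread("fr3", 41L, base_at(20, 30, "C", fill = "G")))
  expect_equal(nrow(collect_fragment_observations(aln3, sites)), 0L)

  # contradictory mates blank the site
  aln4 <- dplyr::bind_rows(
    mkread("fr4", 1L, paste0(base_at(10, 55, "T"), base_at(5, 5, "C", "G"))),
    mkread("fr4", 31L, base_at(30, 40, "G", fill = "G")))
  expect_message(obs4 <- collect_fragment_observations(aln4, sites), "contradictory")
  expect_false(2L %in% obs4$site_id)
})

test_that("parity graph tallies votes and the worked three-site chain resolves trans", {
  # fragments: {1:ALT,2:ALT}, {2:ALT,3:REF}, {2:REF,3:ALT}
  obs <- tibble::tibble(
    fragment_id = c("f1", "f1", "f2", "f2", "f3", "f3"),
    site_id = c(1L, 2L, 2L, 3L, 2L, 3L),
    allele = c("ALT", "ALT", "ALT", "REF", "REF", "ALT"))
  g <- build_phase_graph(obs)
  expect_equal(nrow(g), 2L)
  e12 <- g[g$site_i == 1L, ]
  expect_equal(c(e12$parity, e12$support, e12$conflicts), c("cis", "1", "0"))
  e23 <- g[g$site_i == 2L, ]
  expect_equal(c(e23$parity, e23$support, e23$conflicts), c("trans", "2", "0"))
  # chained call: cis then trans -> trans
  call <- phase_pair(g, 1L, 3L, min_support = 1L)
  expect_equal(call$call, "trans")
  expect_equal(call$path, "1->2->3")
  expect_equal(call$min_support, 1L)

  # symmetry
  expect_equal(phase_pair(g, 3L, 1L, min_support = 1L)$call, "trans")

  # two trans edges chain to cis
  g2 <- build_phase_graph(tibble::tibble(
    fragment_id = c("f1", "f1", "f2", "f2"),
    site_id = c(1L, 2L, 2L, 3L),
    allele = c("ALT", "REF", "ALT", "REF")))
  expect_equal(phase_pair(g2, 1L, 3L, min_support = 1L)$call, "cis")

  # degenerate identical pair
  expect_message(same <- phase_pair(g, 2L, 2L), "identical")
  expect_equal(same$call, "cis")

  # support below threshold -> unresolved
  expect_equal(phase_pair(g, 1L, 3L, min_support = 2L)$call, "unresolved")

  # conflicting votes produce support/conflict counts
  gc <- build_phase_graph(tibble::tibble(
    fragment_id = c("f1", "f1", "f2", "f2"),
    site_id = c(1L, 2L, 1L, 2L),
    allele = c("ALT", "ALT", "ALT", "REF")))
  expect_equal(gc$support, 1L)
  expect_equal(gc$conflicts, 1L)
  # 50% conflict fraction exceeds the default tolerance
  expect_equal(phase_pair(gc, 1L, 2L, min_support = 1L)$call, "unresolved")
})

test_that("disagreeing paths yield unresolved, never a majority vote", {
  # triangle with inconsistent parity: (1,2,cis), (2,3,cis), (1,3,trans)
  obs <- tibble::tibble(
    fragment_id = rep(c("f1", "f2", "f3", "f4", "f5", "f6"), each = 2),
    site_id = c(1L, 2L, 1L, 2L, 2L, 3L, 2L, 3L, 1L, 3L, 1L, 3L),
    allele = c("ALT", "ALT", "ALT", "ALT", "ALT", "ALT", "ALT", "ALT",
               "ALT", "REF", "ALT", "REF"))
  g <- build_phase_graph(obs)
  call <- phase_pair(g, 1L, 3L, min_support = 1L)
  expect_equal(call$call, "unresolved")
  expect_match(call$reason, "disagree")
})

test_that("adding an uninformative fragment never changes a call", {
  obs <- tibble::tibble(
    fragment_id = c("f1", "f1", "f2", "f2", "f3", "f3"),
    site_id = c(1L, 2L, 1L, 2L, 2L, 3L),
    allele = c("ALT", "REF", "ALT", "REF", "ALT", "ALT"))
  base <- phase_pair(build_phase_graph(obs), 1L, 3L, min_support = 1L)
  # a fragment observing one site is dropped upstream; an extra fragment
  # repeating existing evidence does not flip the call either
  more <- dplyr::bind_rows(obs, tibble::tibble(
    fragment_id = c("f4", "f4"), site_id = c(2L, 3L),
    allele = c("ALT", "ALT")))
  again <- phase_pair(build_phase_graph(more), 1L, 3L, min_support = 1L)
  expect_equal(base$call, again$call)
  expect_equal(base$call, "trans")
})

test_that("phase calls match the brute-force minimum-error-correction oracle", {
  set.seed(2024)
  n_checked <- 0L
  for (i in 1:150) {
    inst <- random_phase_instance(sample(3:10, 1), sample(4:30, 1))
    obs <- frag_mat_to_obs(inst$frags)
    g <- build_phase_graph(obs)
    orc <- mec_oracle(inst$frags)
    n <- ncol(inst$frags)
    pairs <- rbind(c(1L, n), t(replicate(2, sort(sample.int(n, 2)))))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      if (a == b) next
      want <- mec_pair_call(orc, a, b)
      got <- phase_pair(g, a, b, min_support = 1L, max_conflict_fraction = 0)$call
      if (want == "ambiguous") {
        expect_equal(got, "unresolved")
      } else {
        expect_equal(got, want)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 300L)
})

test_that("sequencing error is caught by conflict counting, not mistaken for phase", {
  # 1% substitution error; with min_support 2 and the conflict cap, no run
  # may produce a confident wrong call
  wrong <- 0L
  for (run in 1:25) {
    refseq <- make_reference(900, 500 + run)
    v <- tibble::tibble(
      hap = c(1L, 1L, 2L),
      pos = c(200L, 450L, 700L),
      ref = substring(refseq, c(200L, 450L, 700L), c(200L, 450L, 700L)),
      alt = c("A", "C", "G"))
    v$alt <- ifelse(v$alt == v$ref, c("T", "G", "A"), v$alt)
    sim <- simulate_fragments(refseq, v, sim_scenario(depth = 40, error_rate = 0.01),
      seed = 9000 + run, contig = "c")
    sites <- tibble::tibble(site_id = 1:3, contig = "c", pos = v$pos,
      ref = v$ref, alt = v$alt)
    obs <- suppressMessages(collect_fragment_observations(sim$alignments, sites))
    g <- build_phase_graph(obs)
    call <- phase_pair(g, 1L, 3L, min_support = 2L)$call
    if (!call %in% c("trans", "unresolved")) wrong <- wrong + 1L
  }
  expect_equal(wrong, 0L)
})

test_that("end-to-end candidate phasing confirms compound heterozygosity", {
  refseq <- make_reference(1200, 7)
  del_ref <- substr(refseq, 599, 600)
  ins_ref <- substr(refseq, 618, 618)
  v <- tibble::tibble(
    hap = c(1L, 2L),
    pos = c(599L, 618L),
    ref = c(del_ref, ins_ref),
    alt = c(substr(del_ref, 1, 1), paste0(ins_ref, "C")))
  sim <- simulate_fragments(refseq, v, sim_scenario(depth = 50), seed = 11,
    contig = "ctg")
  variants <- tibble::tibble(contig = "ctg", pos = v$pos, ref = v$ref,
    alt = v$alt, gt = "0/1")
  call <- phase_candidates(sim$alignments, variants, "ctg:1-1200",
    candidates = sprintf("ctg:%d:%s:%s", v$pos, v$ref, v$alt))
  expect_equal(call$call, "trans")
  expect_equal(call$conflicts, 0L)
  expect_gte(call$min_support, 2L)
  g <- attr(call, "graph")
  expect_s3_class(glance(g), "tbl_df")
  expect_equal(glance(g)$total_conflicts, 0L)
})
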