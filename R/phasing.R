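#' Read-backed cis/trans phasing
#'
#' When two candidate pathogenic variants are found in the same locus of a
#' recessive disease gene, their clinical interpretation hinges on whether
#' they lie on the same chromosome copy (cis) or on opposite copies (trans,
#' compound heterozygosity). Long amplicons sequenced as short paired-end
#' fragments let the two candidates be connected through chains of
#' informative heterozygous sites: every fragment that co-observes two
#' heterozygous sites votes on their relative parity (same alleles = cis,
#' opposite = trans), and the parity between distant sites is the XOR of
#' parities along a connecting chain.
#'
#' The workflow is [extract_informative_sites()] ->
#' [collect_fragment_observations()] -> [build_phase_graph()] ->
#' [phase_pair()], or [phase_candidates()] end to end.
#'
#' @name lr-phasing
NULL

#' Select informative heterozygous sites in a region
#'
#' Filters variant calls to heterozygous sites inside the region of
#' interest — the candidate variants themselves plus any intervening
#' informative heterozygous variants that can bridge them. Sites whose
#' REF/ALT pair is neither a length-preserving substitution nor a simple
#' left-anchored insertion/deletion are dropped with a warning (they cannot
#' be matched by alignment operations).
#'
#' @param variants Tibble from [read_variants()], or any tibble with
#'   `contig`, `pos`, `ref`, `alt` and either `is_het` or `gt`.
#' @param region Region string `"contig:start-end"` or one-row data frame.
#' @param candidates Optional character vector of `"contig:pos:ref:alt"`
#'   strings naming the candidate variant pair. Each must be present and
#'   heterozygous, otherwise the phasing question is ill-posed and an error
#'   is raised.
#' @return Tibble of sites: `site_id` (1..n in genomic order), `contig`,
#'   `pos`, `ref`, `alt`, `is_candidate`.
#' @export
extract_informative_sites <- function(variants, region, candidates = NULL) {
  reg <- as_region_tbl(region)
  v <- tibble::as_tibble(variants)
  if (!"is_het" %in% names(v)) {
    if (!"gt" %in% names(v)) {
      rlang::abort("variants need an 'is_het' or 'gt' column")
    }
    gt <- gsub("\\|", "/", v$gt)
    v$is_het <- gt %in% c("0/1", "1/0")
  }
  v <- v[v$contig == reg$contig & v$pos >= reg$start & v$pos <= reg$end, ]
  cand_key <- character(0)
  if (!is.null(candidates)) {
    cand_key <- candidates
    for (ck in candidates) {
      p <- strsplit(ck, ":", fixed = TRUE)[[1]]
      if (length(p) != 4L) rlang::abort(sprintf("candidate '%s' not in contig:pos:ref:alt form", ck))
      hit <- v$contig == p[1] & v$pos == as.integer(p[2]) & v$ref == p[3] & v$alt == p[4]
      if (!any(hit)) {
        rlang::abort(sprintf("candidate variant %s not found in region calls", ck))
      }
      if (!any(hit & v$is_het)) {
        rlang::abort(sprintf("candidate variant %s is not heterozygous: phasing is ill-posed", ck))
      }
    }
  }
  v <- v[v$is_het, ]
  ok <- vapply(seq_len(nrow(v)), function(i) !is.null(classify_site(v$ref[i], v$alt[i])), logical(1))
  if (any(!ok)) {
    rlang::warn(sprintf("dropping %d site(s) with complex REF/ALT pairs", sum(!ok)))
  }
  v <- v[ok, ]
  v <- dplyr::arrange(v, .data$pos)
  tibble::tibble(
    site_id = seq_len(nrow(v)),
    contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
    is_candidate = paste(v$contig, v$pos, v$ref, v$alt, sep = ":") %in% cand_key
  )
}

# Site type from the REF/ALT pair: "sub" (equal lengths), "del"
# (ALT is a proper prefix of REF), "ins" (REF is a proper prefix of ALT);
# NULL for anything else.
classify_site <- function(ref, alt) {
  a <- nchar(ref)
  b <- nchar(alt)
  if (ref == alt) return(NULL)
  if (a == b) return("sub")
  if (a > b && substr(ref, 1, b) == alt) return("del")
  if (b > a && substr(alt, 1, a) == ref) return("ins")
  NULL
}

# Allele carried by one read at one site: "REF", "ALT", or NA (missing /
# low quality / mismatching a third allele). `walk` is cigar_walk() output.
read_allele_at_site <- function(walk, seq, quals, ref, alt, pos, min_baseq) {
  type <- classify_site(ref, alt)
  if (is.null(type)) return(NA_character_)
  a <- nchar(ref)
  b <- nchar(alt)
  aligned_base <- function(p) {
    i <- match(p, walk$ref_pos)
    if (is.na(i)) return(NULL)
    idx <- walk$read_idx[i]
    list(base = substr(seq, idx, idx),
         q = if (length(quals) >= idx) quals[idx] else 60L,
         idx = idx)
  }
  span_bases <- function(from, to) {
    bs <- lapply(from:to, aligned_base)
    if (any(vapply(bs, is.null, logical(1)))) return(NULL)
    bs
  }
  if (type == "sub") {
    bs <- span_bases(pos, pos + a - 1L)
    if (is.null(bs)) return(NA_character_)
    if (min(vapply(bs, function(x) x$q, integer(1))) < min_baseq) return(NA_character_)
    obs <- paste(vapply(bs, function(x) x$base, character(1)), collapse = "")
    if (obs == alt) return("ALT")
    if (obs == ref) return("REF")
    return(NA_character_)
  }
  if (type == "del") {
    del_start <- pos + b
    del_end <- pos + a - 1L
    anchor <- span_bases(pos, pos + b - 1L)
    if (is.null(anchor)) return(NA_character_)
    if (min(vapply(anchor, function(x) x$q, integer(1))) < min_baseq) return(NA_character_)
    has_del <- any(walk$dels$start == del_start & walk$dels$end == del_end)
    anchor_str <- paste(vapply(anchor, function(x) x$base, character(1)), collapse = "")
    if (has_del && anchor_str == alt) return("ALT")
    full <- span_bases(pos, del_end)
    touched <- nrow(walk$dels) > 0 &&
      any(walk$dels$start <= del_end & walk$dels$end >= pos)
    if (!is.null(full) && !touched) {
      obs <- paste(vapply(full, function(x) x$base, character(1)), collapse = "")
      if (min(vapply(full, function(x) x$q, integer(1))) < min_baseq) return(NA_character_)
      if (obs == ref) return("REF")
    }
    return(NA_character_)
  }
  # insertion: inserted bases follow reference position pos + a - 1
  after <- pos + a - 1L
  ins_seq <- substr(alt, a + 1L, b)
  anchor <- span_bases(pos, after)
  if (is.null(anchor)) return(NA_character_)
  if (min(vapply(anchor, function(x) x$q, integer(1))) < min_baseq) return(NA_character_)
  hit <- which(walk$ins$after_ref == after)
  if (length(hit) == 1L && walk$ins$len[hit] == b - a) {
    obs_ins <- substr(seq, walk$ins$read_start[hit], walk$ins$read_start[hit] + (b - a) - 1L)
    iq <- quals[walk$ins$read_start[hit]:(walk$ins$read_start[hit] + (b - a) - 1L)]
    if (length(iq) && min(iq) < min_baseq) return(NA_character_)
    if (obs_ins == ins_seq) return("ALT")
    return(NA_character_)
  }
  if (length(hit) == 0L) {
    # REF requires the junction to be observed: the base after the anchor
    # must be aligned contiguously in the read (no insertion in between).
    nxt <- aligned_base(after + 1L)
    if (is.null(nxt)) return(NA_character_)
    if (nxt$q < min_baseq) return(NA_character_)
    return("REF")
  }
  NA_character_
}

#' Collect per-fragment allele observations at heterozygous sites
#'
#' A fragment is a read pair merged by read name (mates jointly observe the
#' haplotype of one source molecule). For each fragment and site, records
#' the allele (`REF`/`ALT`) supported by the alignment: length-preserving
#' substitutions by base identity, insertions and deletions by the
#' alignment operations at the site. Bases under `min_baseq`, reads under
#' `min_mapq`, and mismatches against a third allele yield a missing
#' observation; mates contradicting each other at a site blank that site
#' for the fragment (logged). Fragments observing fewer than two sites are
#' uninformative and dropped.
#'
#' @param alignments Alignment tibble (see [lr-alignments]).
#' @param sites Site tibble from [extract_informative_sites()].
#' @param min_baseq Minimum base quality (default 20).
#' @param min_mapq Minimum mapping quality (default 20).
#' @return Tibble of observations: `fragment_id`, `site_id`, `allele`.
#' @export
collect_fragment_observations <- function(alignments, sites, min_baseq = 20L,
                                          min_mapq = 20L) {
  if (nrow(alignments) == 0L || nrow(sites) == 0L) {
    return(tibble::tibble(fragment_id = character(), site_id = integer(),
      allele = character()))
  }
  aln <- alignments[!is.na(alignments$mapq) & alignments$mapq >= min_mapq, ]
  per_read <- purrr::map(seq_len(nrow(aln)), function(i) {
    r <- aln[i, ]
    cand <- sites[sites$contig == r$rname & sites$pos >= r$pos &
                  sites$pos <= r$pos + nchar(r$seq) + 200L, ]
    if (nrow(cand) == 0L) return(NULL)
    walk <- cigar_walk(r$pos, r$cigar)
    if (length(walk$ref_pos) == 0L) return(NULL)
    quals <- phred_from_qual(r$qual)
    if (length(quals) == 0L) quals <- rep(60L, nchar(r$seq))
    allele <- vapply(seq_len(nrow(cand)), function(j) {
      read_allele_at_site(walk, r$seq, quals, cand$ref[j], cand$alt[j],
        cand$pos[j], min_baseq)
    }, character(1))
    keep <- !is.na(allele)
    if (!any(keep)) return(NULL)
    tibble::tibble(fragment_id = r$qname, site_id = cand$site_id[keep],
      allele = allele[keep])
  })
  obs <- dplyr::bind_rows(per_read)
  if (nrow(obs) == 0L) {
    return(tibble::tibble(fragment_id = character(), site_id = integer(),
      allele = character()))
  }
  # merge mates: contradictory alleles at a site -> missing for the fragment
  merged <- obs %>%
    dplyr::group_by(.data$fragment_id, .data$site_id) %>%
    dplyr::summarise(n_alleles = dplyr::n_distinct(.data$allele),
      allele = .data$allele[1], .groups = "drop")
  n_conflict <- sum(merged$n_alleles > 1L)
  if (n_conflict > 0L) {
    rlang::inform(sprintf(
      "%d site observation(s) with contradictory mate alleles set to missing", n_conflict))
  }
  merged <- merged[merged$n_alleles == 1L, c("fragment_id", "site_id", "allele")]
  merged %>%
    dplyr::group_by(.data$fragment_id) %>%
    dplyr::filter(dplyr::n() >= 2L) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$fragment_id, .data$site_id)
}

#' Build the parity graph over heterozygous sites
#'
#' Every fragment that observes two sites votes on their parity: cis when
#' it carries the same allele class at both (ALT/ALT or REF/REF — a
#' REF/REF co-observation is equally valid evidence between two
#' heterozygous sites), trans when the classes differ. Votes are tallied
#' per site pair; the retained edge takes the majority parity, with
#' `support` the majority count and `conflicts` the minority count.
#'
#' @param observations Tibble from [collect_fragment_observations()].
#' @param sites Optional site tibble, attached to the graph for reporting.
#' @return An `lr_phase_graph`: tibble of edges `site_i`, `site_j`
#'   (`site_i < site_j`), `parity` (`"cis"`/`"trans"`), `support`,
#'   `conflicts`.
#' @export
build_phase_graph <- function(observations, sites = NULL) {
  obs <- tibble::as_tibble(observations)
  edges <- tibble::tibble(site_i = integer(), site_j = integer(),
    parity = character(), support = integer(), conflicts = integer())
  if (nrow(obs) > 0L) {
    votes <- obs %>%
      dplyr::inner_join(obs, by = "fragment_id", relationship = "many-to-many",
        suffix = c("_a", "_b")) %>%
      dplyr::filter(.data$site_id_a < .data$site_id_b) %>%
      dplyr::mutate(vote = ifelse(.data$allele_a == .data$allele_b, "cis", "trans"))
    if (nrow(votes) > 0L) {
      edges <- votes %>%
        dplyr::group_by(site_i = .data$site_id_a, site_j = .data$site_id_b) %>%
        dplyr::summarise(
          cis_n = sum(.data$vote == "cis"),
          trans_n = sum(.data$vote == "trans"),
          .groups = "drop"
        ) %>%
        dplyr::mutate(
          parity = ifelse(.data$cis_n >= .data$trans_n, "cis", "trans"),
          support = pmax(.data$cis_n, .data$trans_n),
          conflicts = pmin(.data$cis_n, .data$trans_n)
        ) %>%
        dplyr::select("site_i", "site_j", "parity", "support", "conflicts")
    }
  }
  attr(edges, "sites") <- sites
  class(edges) <- c("lr_phase_graph", class(edges))
  edges
}

#' Phase a pair of sites through the parity graph
#'
#' Determines the relative phase of two sites as the XOR of edge parities
#' along a connecting path (trans = 1, cis = 0; an odd number of trans
#' edges means trans). Only edges with `support >= min_support` and a
#' conflict fraction `conflicts / (support + conflicts)` at most
#' `max_conflict_fraction` are used. The call is `unresolved` when no such
#' path exists, or when the connected component containing both sites holds
#' parity-inconsistent evidence (two paths would disagree); a diagnostic
#' reason is always reported. Diagnostic use must not overcall, so
#' disagreement is never resolved by majority vote.
#'
#' @param graph An `lr_phase_graph`.
#' @param a,b Site ids (from [extract_informative_sites()]).
#' @param min_support Minimum supporting fragments per edge (default 2).
#' @param max_conflict_fraction Maximum tolerated fraction of conflicting
#'   fragments on an edge (default 0.2).
#' @return One-row tibble: `site_a`, `site_b`, `call`
#'   (`"cis"`/`"trans"`/`"unresolved"`), `path` (site ids joined by `->`),
#'   `min_support` (weakest edge on the path), `conflicts` (total
#'   conflicting fragments on the path), `reason`.
#' @export
phase_pair <- function(graph, a, b, min_support = 2L, max_conflict_fraction = 0.2) {
  a <- as.integer(a)
  b <- as.integer(b)
  result <- function(call, path = NA_character_, minsup = NA_integer_,
                     confl = NA_integer_, reason = NA_character_) {
    tibble::tibble(site_a = a, site_b = b, call = call, path = path,
      min_support = minsup, conflicts = confl, reason = reason)
  }
  if (a == b) {
    rlang::inform("phase_pair called with identical sites: cis by definition")
    return(result("cis", path = as.character(a), minsup = NA_integer_,
      confl = 0L, reason = "degenerate: same site"))
  }
  e <- tibble::as_tibble(graph)
  usable <- e[e$support >= min_support &
              e$conflicts / (e$support + e$conflicts) <= max_conflict_fraction, ]
  if (nrow(usable) == 0L) {
    return(result("unresolved", reason = "no usable edges"))
  }
  nodes <- sort(unique(c(usable$site_i, usable$site_j)))
  if (!(a %in% nodes) || !(b %in% nodes)) {
    return(result("unresolved", reason = "site not connected by any usable edge"))
  }
  # BFS parity labelling from a
  par <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  pred <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  par[as.character(a)] <- 0L
  queue <- a
  while (length(queue) > 0L) {
    u <- queue[1]
    queue <- queue[-1]
    inc <- usable[usable$site_i == u | usable$site_j == u, ]
    for (k in seq_len(nrow(inc))) {
      v <- if (inc$site_i[k] == u) inc$site_j[k] else inc$site_i[k]
      p <- par[as.character(u)] + (inc$parity[k] == "trans")
      if (is.na(par[as.character(v)])) {
        par[as.character(v)] <- p %% 2L
        pred[as.character(v)] <- as.character(u)
        queue <- c(queue, v)
      }
    }
  }
  if (is.na(par[as.character(b)])) {
    return(result("unresolved", reason = "no path between sites"))
  }
  # parity consistency over the whole component containing a and b
  comp <- names(par)[!is.na(par)]
  ce <- usable[as.character(usable$site_i) %in% comp & as.character(usable$site_j) %in% comp, ]
  bad <- (par[as.character(ce$site_i)] + par[as.character(ce$site_j)] +
          (ce$parity == "trans")) %% 2L != 0L
  if (any(bad)) {
    return(result("unresolved",
      reason = sprintf("parity-inconsistent evidence (%d disagreeing edge(s)): paths disagree",
        sum(bad))))
  }
  # reconstruct the BFS path b -> a
  path <- as.character(b)
  while (path[1] != as.character(a)) {
    path <- c(pred[path[1]], path)
  }
  pe <- purrr::map(seq_len(length(path) - 1L), function(k) {
    i <- min(as.integer(path[k]), as.integer(path[k + 1]))
    j <- max(as.integer(path[k]), as.integer(path[k + 1]))
    usable[usable$site_i == i & usable$site_j == j, ]
  }) %>% dplyr::bind_rows()
  call <- if (par[as.character(b)] %% 2L == 1L) "trans" else "cis"
  result(call, path = paste(path, collapse = "->"),
    minsup = min(pe$support), confl = sum(pe$conflicts),
    reason = "consistent parity chain")
}

#' Phase two candidate variants end to end
#'
#' Runs site extraction, fragment observation, graph construction and the
#' pair call in one step.
#'
#' @inheritParams extract_informative_sites
#' @inheritParams collect_fragment_observations
#' @inheritParams phase_pair
#' @param alignments Alignment tibble (see [lr-alignments]).
#' @param candidates Character vector of exactly two
#'   `"contig:pos:ref:alt"` strings.
#' @return One-row tibble as from [phase_pair()], with the candidate
#'   strings in `variant_a` / `variant_b` and the graph in attribute
#'   `graph`.
#' @export
phase_candidates <- function(alignments, variants, region, candidates,
                             min_baseq = 20L, min_mapq = 20L,
                             min_support = 2L, max_conflict_fraction = 0.2) {
  stopifnot(length(candidates) == 2L)
  sites <- extract_informative_sites(variants, region, candidates)
  obs <- collect_fragment_observations(alignments, sites, min_baseq, min_mapq)
  graph <- build_phase_graph(obs, sites)
  ids <- sites$site_id[sites$is_candidate]
  call <- phase_pair(graph, ids[1], ids[2], min_support, max_conflict_fraction)
  call$variant_a <- candidates[1]
  call$variant_b <- candidates[2]
  attr(call, "graph") <- graph
  call
}

#' @export
print.lr_phase_graph <- function(x, ...) {
  cat(sprintf("<lr_phase_graph> %d site(s), %d edge(s), %d conflicting fragment(s)\n",
    length(unique(c(x$site_i, x$site_j))), nrow(x), sum(x$conflicts)))
  NextMethod()
}

#' Tidiers for phase graphs
#'
#' `tidy()` returns the edge table; `glance()` a one-row summary.
#'
#' @param x An `lr_phase_graph`.
#' @param ... Unused.
#' @name lr_phase_graph-tidiers
#' @method tidy lr_phase_graph
#' @export
tidy.lr_phase_graph <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname lr_phase_graph-tidiers
#' @method glance lr_phase_graph
#' @export
glance.lr_phase_graph <- function(x, ...) {
  tibble::tibble(
    n_sites = length(unique(c(x$site_i, x$site_j))),
    n_edges = nrow(x),
    total_support = sum(x$support),
    total_conflicts = sum(x$conflicts)
  )
}
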