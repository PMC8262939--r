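dh <- function(pid, profile, s, e, ev, role = "MTase") {
  data.frame(protein_id = pid, profile_id = profile, env_start = s,
             env_end = e, evalue = ev, role = role, stringsAsFactors = FALSE)
}

pr <- function(pid, genome = "G1", contig = "c1", start = 1, end = 900,
               len = 300) {
  data.frame(protein_id = pid, genome_id = genome, contig_id = contig,
             gene_start = start, gene_end = end, strand = "+", length = len,
             stringsAsFactors = FALSE)
}

no_aln <- data.frame(protein_id = character(0), query_id = character(0),
                     query_length = integer(0), align_length = integer(0),
                     evalue = numeric(0), role = character(0))

test_that("overlapping profiles are competed down to the best E value", {
  # 100% of the shorter envelope overlaps: keep the lower E value
  h <- rbind(dh("p", "A", 1, 100, 1e-10), dh("p", "B", 10, 100, 1e-5))
  expect_equal(compete_profiles(h)$profile_id, "A")
  # 41% overlap of the shorter envelope: both survive
  h <- rbind(dh("p", "A", 1, 100, 1e-10), dh("p", "B", 60, 200, 1e-5))
  expect_equal(nrow(compete_profiles(h)), 2)
  # three mutually overlapping hits: only the best survives
  h <- rbind(dh("p", "A", 1, 100, 1e-3), dh("p", "B", 5, 100, 1e-6),
             dh("p", "C", 1, 95, 1e-9))
  expect_equal(compete_profiles(h)$profile_id, "C")
  # exact threshold: 75% of the shorter envelope counts as overlapping
  h <- rbind(dh("p", "A", 1, 100, 1e-9), dh("p", "B", 26, 125, 1e-4))
  expect_equal(compete_profiles(h)$profile_id, "A")
  h <- rbind(dh("p", "A", 1, 100, 1e-9), dh("p", "B", 27, 126, 1e-4))
  expect_equal(nrow(compete_profiles(h)), 2)
  # E-value tie: the longer envelope wins
  h <- rbind(dh("p", "A", 1, 80, 1e-9), dh("p", "B", 1, 100, 1e-9))
  expect_equal(compete_profiles(h)$profile_id, "B")
  expect_error(compete_profiles(rbind(dh("p", "A", 1, 9, 1e-3),
                                      dh("q", "B", 1, 9, 1e-3))),
               "single protein")
})

test_that("alignment acceptance enforces 75% coverage and the E cutoff", {
  expect_true(accept_alignment(75, 100, 1e-6))
  expect_false(accept_alignment(74, 100, 1e-10))
  expect_false(accept_alignment(90, 100, 1e-4))
  expect_true(accept_alignment(90, 100, 1e-5))     # inclusive E bound
  expect_equal(accept_alignment(c(75, 74), c(100, 100), c(1e-6, 1e-6)),
               c(TRUE, FALSE))
})

test_that("protein role classification follows the size and co-occurrence
           rules", {
  expect_equal(classify_protein(400, c("MTase", "REase")), "fused_RM")
  expect_equal(classify_protein(800, "MTase"), "putative_IIG")
  expect_equal(classify_protein(400, "MTase"), "MTase")
  expect_equal(classify_protein(750, "MTase"), "MTase")  # strict > 750
  expect_equal(classify_protein(751, "MTase"), "putative_IIG")
  expect_equal(classify_protein(300, "REase"), "REase")
  expect_equal(classify_protein(300, "ResIII"), "REase")
  expect_equal(classify_protein(300, c("ResIII", "FP-covariate")), "none")
  # a genuine REase domain is not voided by the covariate rule
  expect_equal(classify_protein(300, c("REase", "FP-covariate")), "REase")
  expect_equal(classify_protein(300, "specificity"), "specificity")
  expect_equal(classify_protein(300, character(0), "MTase"), "MTase")
  expect_equal(classify_protein(300), "none")
})

test_that("pairing respects the 4,000 bp boundary and contig identity", {
  re_mt <- function(gap, contig_mt = "c1") {
    rbind(pr("re1", start = 9101, end = 10000),
          pr("mt1", contig = contig_mt, start = 10000 + gap,
             end = 11000 + gap, len = 350))
  }
  hits <- rbind(dh("re1", "rease_dom", 10, 250, 1e-8, "REase"),
                dh("mt1", "mtase_dom", 10, 300, 1e-9, "MTase"))
  calls <- call_complete_systems(re_mt(4000), hits, no_aln)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "paired")
  expect_equal(calls$members, "mt1;re1")
  expect_equal(nrow(call_complete_systems(re_mt(4001), hits, no_aln)), 0)
  # same coordinates but different contigs: never paired
  expect_equal(nrow(call_complete_systems(re_mt(0, contig_mt = "c2"),
                                          hits, no_aln)), 0)
})

test_that("fused and large MTase-only proteins each yield one call", {
  prot <- rbind(pr("fus1", len = 900),
                pr("big1", start = 50000, end = 53000, len = 1000))
  hits <- rbind(dh("fus1", "mtase_dom", 10, 300, 1e-9, "MTase"),
                dh("fus1", "rease_dom", 400, 700, 1e-7, "REase"),
                dh("big1", "mtase_dom", 50, 350, 1e-9, "MTase"))
  calls <- call_complete_systems(prot, hits, no_aln)
  expect_equal(sort(calls$kind), c("fused", "putative_IIG"))
  counts <- count_rmpg(calls)
  expect_equal(counts$rm_total, 2)
  expect_equal(counts$rm_total_no_iig, 1)
})

test_that("greedy nearest-first pairing is one-to-one", {
  # one MTase flanked by two REases; only the nearer REase pairs
  prot <- rbind(pr("reA", start = 1, end = 900),
                pr("mt1", start = 2000, end = 3000, len = 350),
                pr("reB", start = 3500, end = 4400))
  hits <- rbind(dh("reA", "rease_dom", 10, 250, 1e-8, "REase"),
                dh("reB", "rease_dom", 10, 250, 1e-8, "REase"),
                dh("mt1", "mtase_dom", 10, 300, 1e-9, "MTase"))
  calls <- call_complete_systems(prot, hits, no_aln)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$members, "mt1;reB")   # gap 500 beats gap 1100
})

test_that("counting is invariant to row order and contig renaming", {
  fx <- gen_annotation_fixture(n_genomes = 4, seed = 21)
  base <- count_rmpg(call_complete_systems(fx$proteins, fx$domain_hits,
                                           fx$alignment_hits),
                     genome_ids = fx$truth$genome_id)
  set.seed(1)
  shuf <- fx$proteins[sample(nrow(fx$proteins)), ]
  dshuf <- fx$domain_hits[sample(nrow(fx$domain_hits)), ]
  again <- count_rmpg(call_complete_systems(shuf, dshuf, fx$alignment_hits),
                      genome_ids = fx$truth$genome_id)
  expect_equal(base, again)
  renamed <- fx$proteins
  renamed$contig_id <- paste0("X_", renamed$contig_id)
  ren <- count_rmpg(call_complete_systems(renamed, fx$domain_hits,
                                          fx$alignment_hits),
                    genome_ids = fx$truth$genome_id)
  expect_equal(ren$rm_total, base$rm_total)
})

test_that("planted-truth recovery is exact on adversarial boundary fixtures", {
  for (seed in c(2, 33)) {
    fx <- gen_annotation_fixture(n_genomes = 6, seed = seed)
    calls <- call_complete_systems(fx$proteins, fx$domain_hits,
                                   fx$alignment_hits)
    counts <- count_rmpg(calls, genome_ids = fx$truth$genome_id)
    expect_equal(counts$rm_total, fx$truth$rm_total)
    expect_equal(counts$rm_total_no_iig, fx$truth$rm_total_no_iig)
    # no protein is claimed by two calls
    members <- unlist(strsplit(calls$members, ";"))
    expect_equal(anyDuplicated(members), 0)
    # excluding putative IIG never increases a count
    expect_true(all(counts$rm_total_no_iig <= counts$rm_total))
  }
  # decoy-only genomes yield zero calls
  fx0 <- gen_annotation_fixture(n_genomes = 3, paired = 0, fused = 0,
                                putative_iig = 0, seed = 4)
  expect_equal(fx0$truth$rm_total, rep(0, 3))
  counts <- count_rmpg(call_complete_systems(fx0$proteins, fx0$domain_hits,
                                             fx0$alignment_hits),
                       genome_ids = fx0$truth$genome_id)
  expect_equal(counts$rm_total, rep(0L, 3))
})
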