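#' Generate annotation evidence tables with planted RM systems
#'
#' Builds protein, domain-hit and alignment-hit tables for a set of
#' synthetic genomes in which the number of complete RM systems is known by
#' construction, together with decoys that each violate exactly one calling
#' rule. Planted systems respect the rules with margin (pair gaps at most
#' 3,900 bp, competing duplicate profiles at 80%+ overlap); decoys sit just
#' past a rule boundary (pair gap 4,001 bp, alignment coverage 74%, E value
#' 1.1e-5, a 750-residue MTase-only protein that is deliberately *not* a
#' type IIG candidate because the size rule is strict). Gene blocks are
#' separated by at least 10 kb so no unintended pairing can arise; this is
#' re-validated structurally before returning.
#'
#' @param n_genomes number of genomes.
#' @param paired,fused,putative_iig planted complete systems per genome
#'   (scalar, or length-2 range sampled per genome).
#' @param decoys character vector of decoy kinds planted once per genome;
#'   any of `"orphan_mtase"`, `"orphan_rease"`, `"resIII_fp"`,
#'   `"overlap_duplicate"`, `"gap_4001"`, `"coverage_74"`, `"evalue_high"`,
#'   `"mtase_750"`.
#' @param n_contigs contigs per genome.
#' @param seed integer seed; identical seeds give identical tables.
#' @return A list with data frames `proteins`, `domain_hits`,
#'   `alignment_hits` and `truth` (per-genome `rm_total`,
#'   `rm_total_no_iig`).
#' @export
gen_annotation_fixture <- function(n_genomes = 5, paired = c(0, 3),
                                   fused = c(0, 2), putative_iig = c(0, 2),
                                   decoys = c("orphan_mtase", "orphan_rease",
                                              "resIII_fp", "overlap_duplicate",
                                              "gap_4001", "coverage_74",
                                              "evalue_high", "mtase_750"),
                                   n_contigs = 2, seed = 1L) {
  stopifnot(n_genomes >= 1, n_contigs >= 1)
  known <- c("orphan_mtase", "orphan_rease", "resIII_fp", "overlap_duplicate",
             "gap_4001", "coverage_74", "evalue_high", "mtase_750")
  if (length(setdiff(decoys, known))) {
    stop("unknown decoy kind(s): ",
         paste(setdiff(decoys, known), collapse = ", "))
  }
  set.seed(seed)
  draw_count <- function(x) {
    if (length(x) == 1L) as.integer(x) else sample(x[1]:x[2], 1L)
  }
  prot <- list(); dom <- list(); aln <- list(); truth <- list()
  for (g in seq_len(n_genomes)) {
    gid <- sprintf("G%03d", g)
    cursor <- rep(1L, n_contigs)     # next free coordinate per contig
    serial <- 0L
    new_protein <- function(contig, gene_len_bp, aa_len) {
      serial <<- serial + 1L
      start <- cursor[contig]
      end <- start + gene_len_bp - 1L
      cursor[contig] <<- end + 10000L   # >> 4 kb: blocks never cross-pair
      list(row = data.frame(protein_id = sprintf("%s_p%03d", gid, serial),
                            genome_id = gid,
                            contig_id = sprintf("%s_c%d", gid, contig),
                            gene_start = start, gene_end = end,
                            strand = sample(c("+", "-"), 1L),
                            length = aa_len, stringsAsFactors = FALSE))
    }
    add_dom <- function(pid, profile, s, e, ev, role) {
      dom[[length(dom) + 1L]] <<- data.frame(
        protein_id = pid, profile_id = profile, env_start = s, env_end = e,
        evalue = ev, role = role, stringsAsFactors = FALSE)
    }
    add_aln <- function(pid, query, qlen, alen, ev, role) {
      aln[[length(aln) + 1L]] <<- data.frame(
        protein_id = pid, query_id = query, query_length = qlen,
        align_length = alen, evalue = ev, role = role,
        stringsAsFactors = FALSE)
    }
    n_paired <- draw_count(paired)
    n_fused <- draw_count(fused)
    n_iig <- draw_count(putative_iig)
    for (k in seq_len(n_paired)) {
      contig <- ((k - 1L) %% n_contigs) + 1L
      re <- new_protein(contig, 900L, 300L)
      gap <- sample(0:3900, 1L)
      # place the methyltransferase right after the endonuclease, inside the
      # pairing distance but still inside the reserved block
      mt_start <- re$row$gene_end + gap
      mt <- new_protein(contig, 1050L, 350L)
      mt$row$gene_start <- mt_start
      mt$row$gene_end <- mt_start + 1050L - 1L
      cursor[contig] <- mt$row$gene_end + 10000L
      prot[[length(prot) + 1L]] <- re$row
      prot[[length(prot) + 1L]] <- mt$row
      if (k == 1L) {
        # endonuclease evidence via an accepted reference alignment
        add_aln(re$row$protein_id, "REF_RE1", 280L, 250L, 1e-12, "REase")
      } else if (k == 2L) {
        # endonuclease evidence via a ResIII motif with no covariate
        add_dom(re$row$protein_id, "resIII_motif", 20L, 280L, 1e-9, "ResIII")
      } else {
        add_dom(re$row$protein_id, "rease_dom", 20L, 280L, 1e-9, "REase")
      }
      add_dom(mt$row$protein_id, "mtase_dom", 10L, 320L, 1e-11, "MTase")
    }
    for (k in seq_len(n_fused)) {
      p <- new_protein(((k - 1L) %% n_contigs) + 1L, 2700L, 900L)
      prot[[length(prot) + 1L]] <- p$row
      add_dom(p$row$protein_id, "mtase_dom", 20L, 320L, 1e-14, "MTase")
      add_dom(p$row$protein_id, "rease_dom", 420L, 820L, 1e-8, "REase")
    }
    for (k in seq_len(n_iig)) {
      aa <- sample(760:1200, 1L)
      p <- new_protein(((k - 1L) %% n_contigs) + 1L, aa * 3L, aa)
      prot[[length(prot) + 1L]] <- p$row
      add_dom(p$row$protein_id, "mtase_dom", 50L, 400L, 1e-13, "MTase")
    }
    for (dk in decoys) {
      contig <- sample(n_contigs, 1L)
      if (dk == "orphan_mtase") {
        p <- new_protein(contig, 1050L, 350L)
        prot[[length(prot) + 1L]] <- p$row
        add_dom(p$row$protein_id, "mtase_dom", 10L, 300L, 1e-10, "MTase")
      } else if (dk == "orphan_rease") {
        p <- new_protein(contig, 900L, 300L)
        prot[[length(prot) + 1L]] <- p$row
        add_dom(p$row$protein_id, "rease_dom", 15L, 270L, 1e-9, "REase")
      } else if (dk == "resIII_fp") {
        # ResIII motif voided by a co-occurring false-positive covariate
        p <- new_protein(contig, 1800L, 600L)
        prot[[length(prot) + 1L]] <- p$row
        add_dom(p$row$protein_id, "resIII_motif", 30L, 290L, 1e-12, "ResIII")
        add_dom(p$row$protein_id, "helicase_cov", 320L, 580L, 1e-15,
                "FP-covariate")
      } else if (dk == "overlap_duplicate") {
        # a worse-E profile at >= 80% overlap on an orphan MTase: the
        # duplicate is competed away, the orphan still yields no call
        p <- new_protein(contig, 1050L, 350L)
        prot[[length(prot) + 1L]] <- p$row
        add_dom(p$row$protein_id, "mtase_dom", 10L, 300L, 1e-10, "MTase")
        add_dom(p$row$protein_id, "mtase_dom_alt", 40L, 300L, 1e-4, "MTase")
      } else if (dk == "gap_4001") {
        re <- new_protein(contig, 900L, 300L)
        mt_start <- re$row$gene_end + 4001L
        mt <- new_protein(contig, 1050L, 350L)
        mt$row$gene_start <- mt_start
        mt$row$gene_end <- mt_start + 1050L - 1L
        cursor[contig] <- mt$row$gene_end + 10000L
        prot[[length(prot) + 1L]] <- re$row
        prot[[length(prot) + 1L]] <- mt$row
        add_dom(re$row$protein_id, "rease_dom", 20L, 280L, 1e-9, "REase")
        add_dom(mt$row$protein_id, "mtase_dom", 10L, 320L, 1e-11, "MTase")
      } else if (dk == "coverage_74") {
        p <- new_protein(contig, 1200L, 400L)
        prot[[length(prot) + 1L]] <- p$row
        add_aln(p$row$protein_id, "REF_MT9", 100L, 74L, 1e-10, "MTase")
      } else if (dk == "evalue_high") {
        p <- new_protein(contig, 1200L, 400L)
        prot[[length(prot) + 1L]] <- p$row
        add_aln(p$row$protein_id, "REF_MT9", 100L, 90L, 1.1e-5, "MTase")
      } else if (dk == "mtase_750") {
        # exactly 750 aa, MTase-only: size rule is strict, so an orphan
        p <- new_protein(contig, 2250L, 750L)
        prot[[length(prot) + 1L]] <- p$row
        add_dom(p$row$protein_id, "mtase_dom", 50L, 400L, 1e-13, "MTase")
      }
    }
    truth[[g]] <- data.frame(genome_id = gid,
                             rm_total = n_paired + n_fused + n_iig,
                             rm_total_no_iig = n_paired + n_fused,
                             stringsAsFactors = FALSE)
  }
  empty_dom <- data.frame(protein_id = character(0), profile_id = character(0),
                          env_start = integer(0), env_end = integer(0),
                          evalue = numeric(0), role = character(0),
                          stringsAsFactors = FALSE)
  empty_aln <- data.frame(protein_id = character(0), query_id = character(0),
                          query_length = integer(0), align_length = integer(0),
                          evalue = numeric(0), role = character(0),
                          stringsAsFactors = FALSE)
  out <- list(proteins = do.call(rbind, prot),
              domain_hits = if (length(dom)) do.call(rbind, dom) else empty_dom,
              alignment_hits = if (length(aln)) do.call(rbind, aln) else empty_aln,
              truth = do.call(rbind, truth))
  validate_fixture_margins(out)
  out
}

# structural check that no decoy can accidentally satisfy the pairing rule:
# enzyme-bearing genes of different planted blocks must sit > 4,000 bp apart
validate_fixture_margins <- function(fx) {
  ev_prot <- unique(c(fx$domain_hits$protein_id, fx$alignment_hits$protein_id))
  p <- fx$proteins[fx$proteins$protein_id %in% ev_prot, , drop = FALSE]
  for (ct in unique(p$contig_id)) {
    d <- p[p$contig_id == ct, , drop = FALSE]
    d <- d[order(d$gene_start), , drop = FALSE]
    if (nrow(d) < 2) next
    gaps <- d$gene_start[-1] - d$gene_end[-nrow(d)]
    near <- which(gaps <= 4000)
    for (i in near) {
      pair <- sort(d$protein_id[c(i, i + 1)])
      # adjacency inside one planted paired block is expected; anything else
      # would corrupt the planted truth
      same_block <- diff(as.integer(sub(".*_p", "", pair))) == 1L
      if (!same_block) {
        stop("fixture generation produced an unintended near-pair: ",
             paste(pair, collapse = " / "))
      }
    }
  }
  invisible(fx)
}

#' Generate isolate and genus tables with known statistical structure
#'
#' Draws isolate-level RM counts from a stated generating model given genome
#' size, so regression and summary routines can be checked for parameter
#' recovery.
#'
#' @param n_genera number of genera.
#' @param isolates_per_genus scalar or length-2 range.
#' @param size_range_mbp genome-size range (uniform) in Mbp.
#' @param model `"negbin"` (counts from a log-link NB:
#'   `mu = exp(intercept + slope * size_mbp)`, dispersion `theta`) or
#'   `"linear"` (`rm = intercept + slope * size_mbp + N(0, noise_sd)`,
#'   truncated at 0).
#' @param intercept,slope,theta,noise_sd generating parameters.
#' @param group_shift additive RM-count shift applied to the second half of
#'   the genera (labelled habitat `"eutrophic"` vs `"oligotrophic"`), for
#'   two-group comparisons.
#' @param iig_fraction expected fraction of each isolate's systems that are
#'   putative type IIG (binomially thinned to form `rm_total_no_iig`).
#' @param seed integer seed.
#' @return A list with `isolates`, `genus` (via [aggregate_genus()]) and
#'   `truth` (the generating parameters).
#' @export
gen_stats_tables <- function(n_genera = 50, isolates_per_genus = c(1, 20),
                             size_range_mbp = c(1, 10),
                             model = c("negbin", "linear"),
                             intercept = 0.5, slope = 0.1, theta = 2,
                             noise_sd = 1, group_shift = 0,
                             iig_fraction = 0.25, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_genera >= 2, theta > 0, size_range_mbp[1] > 0)
  set.seed(seed)
  ni <- if (length(isolates_per_genus) == 1L) {
    rep(isolates_per_genus, n_genera)
  } else {
    sample(isolates_per_genus[1]:isolates_per_genus[2], n_genera,
           replace = TRUE)
  }
  genus <- rep(sprintf("Genus%04d", seq_len(n_genera)), ni)
  habitat <- rep(ifelse(seq_len(n_genera) > n_genera / 2,
                        "eutrophic", "oligotrophic"), ni)
  n_iso <- sum(ni)
  size_mbp <- stats::runif(n_iso, size_range_mbp[1], size_range_mbp[2])
  shift <- ifelse(habitat == "eutrophic", group_shift, 0)
  counts <- if (model == "negbin") {
    stats::rnbinom(n_iso, size = theta,
                   mu = exp(intercept + slope * size_mbp)) + shift
  } else {
    pmax(0, round(intercept + slope * size_mbp +
                    stats::rnorm(n_iso, 0, noise_sd) + shift))
  }
  iig <- stats::rbinom(n_iso, size = counts, prob = iig_fraction)
  isolates <- data.frame(
    assembly_id = paste0(genus, "_a", unlist(lapply(ni, seq_len))),
    genus = genus, phylum = "SynthPhylum",
    genome_size = round(size_mbp * 1e6),
    rm_total = counts, rm_total_no_iig = counts - iig,
    habitat = habitat, stringsAsFactors = FALSE)
  list(isolates = isolates,
       genus = aggregate_genus(isolates),
       truth = list(model = model, intercept = intercept, slope = slope,
                    theta = theta, noise_sd = noise_sd,
                    group_shift = group_shift, iig_fraction = iig_fraction,
                    seed = seed))
}
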