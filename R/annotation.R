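#' Resolve overlapping profile hits on one protein
#'
#' Profile HMM hits that align to largely the same residues of a protein are
#' redundant descriptions of one motif. Hits whose envelopes overlap by at
#' least 75% of the shorter envelope are "competed": the hit with the lower
#' E value is retained and the other discarded, iterating until no pair
#' overlaps at or above the threshold. E-value ties are broken in favour of
#' the longer envelope, then the lexicographically smaller profile id.
#'
#' @param hits data frame of domain hits for a single protein with columns
#'   `protein_id`, `profile_id`, `env_start`, `env_end`, `evalue` (and
#'   optionally `role`).
#' @param overlap_frac competing threshold, default 0.75.
#' @return The retained rows of `hits`.
#' @examples
#' h <- data.frame(protein_id = "p1", profile_id = c("A", "B"),
#'                 env_start = c(1, 10), env_end = c(100, 100),
#'                 evalue = c(1e-10, 1e-5))
#' compete_profiles(h)$profile_id  # "A"
#' @export
compete_profiles <- function(hits, overlap_frac = 0.75) {
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$protein_id)) != 1L) {
    stop("compete_profiles expects hits from a single protein")
  }
  len <- hits$env_end - hits$env_start + 1L
  # best-first retention is equivalent to iterative pairwise elimination:
  # a hit is discarded iff a strictly better retained hit overlaps it
  ord <- order(hits$evalue, -len, hits$profile_id)
  keep <- logical(nrow(hits))
  for (i in ord) {
    kept <- which(keep)
    clash <- FALSE
    for (k in kept) {
      ov <- min(hits$env_end[i], hits$env_end[k]) -
        max(hits$env_start[i], hits$env_start[k]) + 1L
      if (ov > 0 && ov / min(len[i], len[k]) >= overlap_frac) {
        clash <- TRUE
        break
      }
    }
    if (!clash) keep[i] <- TRUE
  }
  hits[keep, , drop = FALSE]
}

#' Accept or reject a reference-protein alignment hit
#'
#' BLAST-style alignments to reference enzymes lacking diagnostic profiles
#' count as evidence only when the alignment covers at least 75% of the
#' query (reference) length and the E value is at most 1e-5.
#'
#' @param align_length alignment length in residues.
#' @param query_length reference protein length in residues.
#' @param evalue alignment E value.
#' @return Logical vector (vectorized over its arguments).
#' @examples
#' accept_alignment(75, 100, 1e-6)   # TRUE  (boundary coverage)
#' accept_alignment(74, 100, 1e-10)  # FALSE
#' @export
accept_alignment <- function(align_length, query_length, evalue) {
  stopifnot(all(align_length > 0), all(query_length > 0), all(evalue >= 0))
  align_length >= 0.75 * query_length & evalue <= 1e-5
}

# evidence roles recognized in the hit tables
.mtase_roles <- "MTase"
.rease_roles <- "REase"

#' Classify a protein's RM role from its retained evidence
#'
#' Combines competed domain-hit roles and accepted alignment-hit roles into
#' one functional call per protein:
#' * methyltransferase and endonuclease evidence on one peptide: `fused_RM`
#'   (a single-polypeptide, type IIG-like system);
#' * methyltransferase only, longer than 750 amino acids: `putative_IIG`
#'   (large MTase-only proteins are candidate type IIG enzymes);
#' * methyltransferase only otherwise: `MTase`; endonuclease only: `REase`;
#' * `ResIII`-type endonuclease evidence is voided when any false-positive
#'   covariate domain co-occurs on the same protein (ResIII motifs recur in
#'   helicases and regulators that are not RM components);
#' * specificity-subunit evidence alone: `specificity`; nothing: `none`.
#'
#' @param length protein length in amino acids.
#' @param domain_roles character vector of retained domain-hit roles, from
#'   `{"MTase", "REase", "specificity", "ResIII", "FP-covariate"}`.
#' @param alignment_roles character vector of accepted alignment-hit roles,
#'   from `{"MTase", "REase"}`.
#' @param iig_min_length size above which an MTase-only protein is a
#'   type IIG candidate (amino acids; the cut is strict, `length > 750`).
#' @return One of `"fused_RM"`, `"putative_IIG"`, `"MTase"`, `"REase"`,
#'   `"specificity"`, `"none"`.
#' @export
classify_protein <- function(length, domain_roles = character(0),
                             alignment_roles = character(0),
                             iig_min_length = 750) {
  stopifnot(length > 0)
  has_fp <- any(domain_roles == "FP-covariate")
  resIII_ok <- any(domain_roles == "ResIII") && !has_fp
  has_mtase <- any(domain_roles %in% .mtase_roles) ||
    any(alignment_roles %in% .mtase_roles)
  has_rease <- any(domain_roles %in% .rease_roles) ||
    any(alignment_roles %in% .rease_roles) || resIII_ok
  has_spec <- any(domain_roles == "specificity")
  if (has_mtase && has_rease) return("fused_RM")
  if (has_mtase) {
    return(if (length > iig_min_length) "putative_IIG" else "MTase")
  }
  if (has_rease) return("REase")
  if (has_spec) return("specificity")
  "none"
}

# run compete_profiles per protein and accept_alignment filtering, then
# classify every protein in the table
classify_genome_proteins <- function(proteins, domain_hits, alignment_hits) {
  dh <- if (nrow(domain_hits)) {
    do.call(rbind, lapply(split(domain_hits, domain_hits$protein_id),
                          compete_profiles))
  } else {
    domain_hits
  }
  ah <- if (nrow(alignment_hits)) {
    keep <- accept_alignment(alignment_hits$align_length,
                             alignment_hits$query_length,
                             alignment_hits$evalue)
    alignment_hits[keep, , drop = FALSE]
  } else {
    alignment_hits
  }
  roles <- vapply(seq_len(nrow(proteins)), function(i) {
    pid <- proteins$protein_id[i]
    classify_protein(proteins$length[i],
                     domain_roles = dh$role[dh$protein_id == pid],
                     alignment_roles = ah$role[ah$protein_id == pid])
  }, character(1))
  cbind(proteins, role = roles, stringsAsFactors = FALSE)
}

gene_gap <- function(s1, e1, s2, e2) {
  # bp between closest gene boundaries; 0 when intervals touch or overlap
  max(0L, max(s1, s2) - min(e1, e2))
}

#' Call complete RM systems in annotated genomes
#'
#' Applies the genomic-context completeness rule to classified proteins. A
#' complete system is: a fused (MTase+REase) peptide; a putative type IIG
#' peptide; or an endonuclease at most `max_gap` bp from a methyltransferase
#' on the same contig. Pairing is greedy nearest-first and one-to-one: the
#' closest eligible REase-MTase pair is called first and its members removed
#' from further pairing. Unpaired enzymes yield no call.
#'
#' @param proteins data frame with columns `protein_id`, `genome_id`,
#'   `contig_id`, `gene_start`, `gene_end`, `strand`, `length` (1-based
#'   inclusive coordinates).
#' @param domain_hits data frame with columns `protein_id`, `profile_id`,
#'   `env_start`, `env_end`, `evalue`, `role`.
#' @param alignment_hits data frame with columns `protein_id`, `query_id`,
#'   `query_length`, `align_length`, `evalue`, `role`.
#' @param max_gap maximum gap (bp) between the closest gene boundaries of a
#'   paired endonuclease and methyltransferase; the bound is inclusive.
#' @return A data frame of calls: `genome_id`, `kind` (`"paired"`,
#'   `"fused"`, `"putative_IIG"`), `members` (protein ids, `;`-separated).
#' @export
call_complete_systems <- function(proteins, domain_hits, alignment_hits,
                                  max_gap = 4000) {
  req <- c("protein_id", "genome_id", "contig_id", "gene_start", "gene_end",
           "length")
  if (!all(req %in% names(proteins))) {
    stop("proteins table lacks column(s): ",
         paste(setdiff(req, names(proteins)), collapse = ", "))
  }
  if (any(proteins$gene_start > proteins$gene_end)) {
    stop("gene_start must be <= gene_end")
  }
  # deterministic regardless of input row order
  proteins <- proteins[order(proteins$genome_id, proteins$contig_id,
                             proteins$gene_start, proteins$protein_id), ,
                       drop = FALSE]
  classified <- classify_genome_proteins(proteins, domain_hits, alignment_hits)
  calls <- list()
  single <- classified[classified$role %in% c("fused_RM", "putative_IIG"), ,
                       drop = FALSE]
  if (nrow(single)) {
    calls[[length(calls) + 1L]] <- data.frame(
      genome_id = single$genome_id,
      kind = ifelse(single$role == "fused_RM", "fused", "putative_IIG"),
      members = single$protein_id, stringsAsFactors = FALSE)
  }
  enzymes <- classified[classified$role %in% c("MTase", "REase"), ,
                        drop = FALSE]
  for (key in unique(paste(enzymes$genome_id, enzymes$contig_id, sep = "\r"))) {
    sub <- enzymes[paste(enzymes$genome_id, enzymes$contig_id, sep = "\r") ==
                     key, , drop = FALSE]
    re <- sub[sub$role == "REase", , drop = FALSE]
    mt <- sub[sub$role == "MTase", , drop = FALSE]
    if (!nrow(re) || !nrow(mt)) next
    pairs <- expand.grid(ri = seq_len(nrow(re)), mi = seq_len(nrow(mt)))
    pairs$gap <- mapply(function(ri, mi) {
      gene_gap(re$gene_start[ri], re$gene_end[ri],
               mt$gene_start[mi], mt$gene_end[mi])
    }, pairs$ri, pairs$mi)
    pairs <- pairs[pairs$gap <= max_gap, , drop = FALSE]
    if (!nrow(pairs)) next
    pairs <- pairs[order(pairs$gap, re$protein_id[pairs$ri],
                         mt$protein_id[pairs$mi]), , drop = FALSE]
    used_r <- logical(nrow(re)); used_m <- logical(nrow(mt))
    for (k in seq_len(nrow(pairs))) {
      ri <- pairs$ri[k]; mi <- pairs$mi[k]
      if (used_r[ri] || used_m[mi]) next
      used_r[ri] <- TRUE; used_m[mi] <- TRUE
      calls[[length(calls) + 1L]] <- data.frame(
        genome_id = re$genome_id[ri], kind = "paired",
        members = paste(sort(c(re$protein_id[ri], mt$protein_id[mi])),
                        collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) {
    return(data.frame(genome_id = character(0), kind = character(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$genome_id, out$kind, out$members), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count RM systems per genome
#'
#' @param calls a call table from [call_complete_systems()].
#' @param genome_ids optional vector of genomes to report (so genomes with
#'   zero calls appear with count 0).
#' @return A data frame with columns `genome_id`, `rm_total` and
#'   `rm_total_no_iig` (the count excluding putative type IIG calls, the
#'   stricter sensitivity variant).
#' @export
count_rmpg <- function(calls, genome_ids = NULL) {
  ids <- sort(unique(c(genome_ids, calls$genome_id)))
  total <- vapply(ids, function(g) sum(calls$genome_id == g), integer(1))
  no_iig <- vapply(ids, function(g) {
    sum(calls$genome_id == g & calls$kind != "putative_IIG")
  }, integer(1))
  data.frame(genome_id = ids, rm_total = total, rm_total_no_iig = no_iig,
             stringsAsFactors = FALSE, row.names = NULL)
}
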