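#' Run the duplication + GRINS analysis on one cluster
#'
#' Orchestrates the full scan: window segmentation, all-vs-all best
#' identity profile, skew profile, duplicated-region calling, and GRINS
#' promotion. With `out_dir` set, writes the artifact set (profile and
#' skew TSVs, duplicated-region and GRINS BED6 tracks, a candidate table,
#' the input echoed as FASTA, and a JSON run manifest with all parameters
#' and the input digest). Outputs are deterministic: rerunning with the
#' same inputs and parameters is byte-identical.
#'
#' A cluster shorter than one window yields empty outputs with a warning
#' (not an error).
#'
#' @param cluster A `gene_cluster`.
#' @param params A [scan_params()] object.
#' @param skew_min Mean-absolute-skew threshold for GRINS.
#' @param rule `"both"` or `"either"` (see [call_grins()]).
#' @param out_dir Optional output directory (created if needed).
#' @return List with `profile`, `skews`, `dups`, `grins` and `manifest`.
#' @export
run_grins_pipeline <- function(cluster, params = scan_params(),
                               skew_min = 0.15, rule = "both",
                               out_dir = NULL) {
  stopifnot(inherits(cluster, "gene_cluster"))
  if (cluster$length < params$win_len)
    warning("cluster (", cluster$length, " bp) shorter than one window (",
            params$win_len, " bp); outputs are empty")
  profile <- max_identity_profile(cluster, params)
  skews <- skew_profile(cluster, params)
  dups <- call_duplicated_regions(profile, params)
  grins <- call_grins(dups, skews, skew_min = skew_min, rule = rule)
  manifest <- list(
    tool = "grinscan", version = as.character(packageVersion("grinscan")),
    stage = "grins",
    cluster = list(id = cluster$id, length = cluster$length),
    params = unclass(params), skew_min = skew_min, rule = rule)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(out_dir, "cluster.fasta")
    writeLines(c(paste0(">", cluster$id), cluster$seq), fa)
    manifest$cluster$md5 <- unname(tools::md5sum(fa))
    prof_df <- data.frame(
      window_index = profile$windows$index,
      start = profile$windows$start, end = profile$windows$end,
      best_identity = profile$best_identity,
      best_partner_start =
        ifelse(is.na(profile$best_partner), NA_integer_,
               profile$windows$start[profile$best_partner]))
    write.table(prof_df, file.path(out_dir, "identity_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(skews), file.path(out_dir, "skew_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dup_bed <- dups
    dup_bed$name <- if (nrow(dups)) sprintf("dup_%d", seq_len(nrow(dups)))
                    else character(0)
    dup_bed$score <- dups$mean_identity
    write_bed(dup_bed, file.path(out_dir, "duplicated_regions.bed"),
              chrom = cluster$id)
    pass <- grins[grins$passes, , drop = FALSE]
    pass_bed <- pass
    pass_bed$name <- if (nrow(pass)) sprintf("GRINS_%d", seq_len(nrow(pass)))
                     else character(0)
    # skew magnitude on the 0-100 scale so the BED score is skew * 1000
    pass_bed$score <- 100 * (pass$mean_abs_gc + pass$mean_abs_ta) / 2
    write_bed(pass_bed, file.path(out_dir, "grins.bed"), chrom = cluster$id)
    write.table(grins, file.path(out_dir, "grins_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(profile = profile, skews = skews, dups = dups, grins = grins,
       manifest = manifest)
}

#' Run the module/domain phylogeny analysis
#'
#' Computes pairwise Jukes-Cantor distances over module or domain
#' sequences (codon-aware pairwise alignment by default, or column
#' slicing of a supplied alignment), builds the neighbor-joining tree,
#' and answers optional topology queries. With `out_dir` set, writes the
#' Newick tree, the distance matrix TSV, a query summary TSV and a JSON
#' manifest. A saturated pair (p >= 0.75) aborts with the pair named,
#' unless `cap = TRUE`.
#'
#' @param seqs Named character vector of nucleotide sequences, or a path
#'   to a multi-FASTA file.
#' @param aligned The sequences are rows of one alignment; distances use
#'   column slicing with pairwise deletion instead of codon alignment.
#' @param sisters Optional `c(a, b)` leaf pair for a cherry query.
#' @param classes Optional named vector mapping every leaf to one of two
#'   classes for a [split_consistent()] query (e.g. ATa vs ATp modules).
#' @param cap Cap saturated distances at 5.0 instead of erroring.
#' @param out_dir Optional output directory.
#' @return List with `distances`, `tree`, `sisters` (flag or `NA`),
#'   `split` (flag or `NA`) and `manifest`.
#' @export
run_phylo_pipeline <- function(seqs, aligned = FALSE, sisters = NULL,
                               classes = NULL, cap = FALSE, out_dir = NULL) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs)) {
    recs <- Biostrings::readBStringSet(seqs)
    seqs <- setNames(as.character(recs), sub("\\s.*$", "", names(recs)))
  }
  if (length(seqs) < 2) stop("need at least 2 region sequences")
  D <- dist_jc(seqs, method = if (aligned) "aligned" else "codon", cap = cap)
  tree <- nj_tree(D)
  sis <- if (!is.null(sisters)) is_sister_pair(tree, sisters[1], sisters[2])
         else NA
  spl <- if (!is.null(classes)) split_consistent(tree, classes) else NA
  manifest <- list(
    tool = "grinscan", version = as.character(packageVersion("grinscan")),
    stage = "phylo", n_sequences = length(seqs), aligned = aligned,
    cap = cap,
    sisters = if (is.null(sisters)) NULL else as.list(sisters),
    distance_model = "jukes-cantor", tree_method = "neighbor-joining")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    write.table(round(D, 6), file.path(out_dir, "distances.tsv"),
                sep = "\t", quote = FALSE)
    qs <- data.frame(query = character(), answer = character(),
                     stringsAsFactors = FALSE)
    if (!is.null(sisters))
      qs <- rbind(qs, data.frame(
        query = paste0("sisters:", sisters[1], ",", sisters[2]),
        answer = as.character(sis)))
    if (!is.null(classes))
      qs <- rbind(qs, data.frame(query = "split_consistent",
                                 answer = as.character(spl)))
    write.table(qs, file.path(out_dir, "queries.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(distances = D, tree = tree, sisters = sis, split = spl,
       manifest = manifest)
}
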