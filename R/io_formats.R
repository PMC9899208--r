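#' Read a gene-cluster nucleotide sequence
#'
#' Reads the first nucleotide record of a FASTA or GenBank file into a
#' `gene_cluster` object. The sequence is uppercased, `U` is mapped to `T`,
#' and IUPAC ambiguity codes other than `N` are mapped to `N` with a
#' warning. Files whose residues look like protein (more than 10% of
#' characters outside `{A,C,G,T,N}`) are rejected.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"genbank"`.
#' @return A `gene_cluster` object: a list with elements `id`, `seq`
#'   (uppercase ACGTN string), `length` (bp) and `source`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy", "ACGTACGTAC"), fa)
#' read_cluster(fa)
#' @export
read_cluster <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genbank") {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    ok <- tryCatch({
      seqinr::gb2fasta(path, tmp)
      TRUE
    }, error = function(e) FALSE)
    if (!ok || !file.exists(tmp) || file.size(tmp) == 0)
      stop("no sequence records in GenBank file: ", path)
    path <- tmp
  }
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("no sequence records in ", path))
  if (length(recs) == 0) stop("no sequence records in ", path)
  if (length(recs) > 1)
    warning(length(recs), " records in ", path, "; using the first only")
  id <- sub("\\s.*$", "", names(recs)[1L])
  if (!nzchar(id)) stop("first record has an empty id")
  gene_cluster(id, as.character(recs[[1L]]), source = format)
}

#' Construct a gene-cluster record from an in-memory sequence
#'
#' @param id Non-empty sequence label.
#' @param seq Nucleotide string; normalized as in [read_cluster()].
#' @param source Provenance tag, `"fasta"` or `"genbank"`.
#' @return A `gene_cluster` object.
#' @export
gene_cluster <- function(id, seq, source = c("fasta", "genbank")) {
  source <- match.arg(source)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- normalize_nt(seq, what = paste0("record '", id, "'"))
  structure(list(id = id, seq = seq, length = nchar(seq), source = source),
            class = "gene_cluster")
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster> %s: %d bp (%s)\n", x$id, x$length, x$source))
  invisible(x)
}

REGION_KINDS <- c("module", "domain")
DOMAIN_CLASSES <- c("KS", "AT", "DH", "ER", "KR", "ACP", "TE", "none")

#' Read module/domain region annotations
#'
#' Reads a region table in either a 7-column TSV dialect (`name`, `kind`,
#' `domain_class`, `start`, `end`, `strand`, optional `frame_offset`;
#' coordinates 1-based inclusive) or GFF3 (type column gives the kind;
#' attributes `Name` and `domain_class` carry the labels). Returned
#' coordinates are 0-based half-open, sorted by start, and validated
#' against the cluster length.
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param cluster The `gene_cluster` the annotations describe.
#' @return A data frame with columns `name`, `kind`, `domain_class`,
#'   `start`, `end`, `strand`, `frame_offset` (0-based half-open).
#' @export
read_regions <- function(path, dialect = c("tsv", "gff3"), cluster) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     comment.char = "#")
    if (is.null(df$frame_offset)) df$frame_offset <- 0L
    out <- data.frame(name = as.character(df$name),
                      kind = as.character(df$kind),
                      domain_class = as.character(df$domain_class),
                      start = as.integer(df$start) - 1L,
                      end = as.integer(df$end),
                      strand = as.character(df$strand),
                      frame_offset = as.integer(df$frame_offset),
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    nm <- if ("Name" %in% names(mc)) as.character(mc$Name) else NA_character_
    if (anyNA(nm)) stop("GFF3 record without a Name attribute")
    dc <- if ("domain_class" %in% names(mc)) as.character(mc$domain_class)
          else rep(NA_character_, length(gr))
    dc[is.na(dc)] <- "none"
    ph <- if ("phase" %in% names(mc)) as.integer(mc$phase) else
      rep(NA_integer_, length(gr))
    ph[is.na(ph)] <- 0L
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    out <- data.frame(name = nm,
                      kind = as.character(mc$type),
                      domain_class = dc,
                      start = BiocGenerics::start(gr) - 1L,
                      end = BiocGenerics::end(gr),
                      strand = strand,
                      frame_offset = ph,
                      stringsAsFactors = FALSE)
  }
  region_annotations(out, cluster$length)
}

#' Validate and sort a region-annotation table
#'
#' Enforces the coordinate and label invariants used throughout the
#' package: 0-based half-open intervals inside the cluster, known kinds and
#' domain classes, and `domain_class == "none"` exactly for modules.
#'
#' @param df Data frame with columns `name`, `kind`, `domain_class`,
#'   `start`, `end`, `strand` and optionally `frame_offset`.
#' @param cluster_length Cluster length in bp.
#' @return The validated data frame, sorted by `start`.
#' @export
region_annotations <- function(df, cluster_length) {
  need <- c("name", "kind", "domain_class", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing region columns: ", paste(miss, collapse = ", "))
  if (is.null(df$frame_offset)) df$frame_offset <- 0L
  if (any(!nzchar(df$name))) stop("empty region name")
  bad_kind <- setdiff(unique(df$kind), REGION_KINDS)
  if (length(bad_kind)) stop("unknown region kind: ", bad_kind[1])
  bad_dc <- setdiff(unique(df$domain_class), DOMAIN_CLASSES)
  if (length(bad_dc)) stop("unknown domain_class token: ", bad_dc[1])
  mism <- (df$kind == "module") != (df$domain_class == "none")
  if (any(mism))
    stop("domain_class must be 'none' for modules and a domain class for ",
         "domains (offending region: ", df$name[which(mism)[1]], ")")
  if (any(df$end <= df$start))
    stop("region with end <= start: ", df$name[which(df$end <= df$start)[1]])
  if (any(df$start < 0 | df$end > cluster_length))
    stop("region outside cluster bounds: ",
         df$name[which(df$start < 0 | df$end > cluster_length)[1]])
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(df$frame_offset %in% 0:2)) stop("frame_offset must be 0, 1 or 2")
  df <- df[order(df$start, df$end, df$name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write region annotations as TSV
#'
#' Inverse of the TSV dialect of [read_regions()]: 1-based inclusive
#' coordinates, one header line.
#'
#' @param regions Region data frame (0-based half-open).
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  out <- regions[, c("name", "kind", "domain_class", "start", "end",
                     "strand", "frame_offset")]
  out$start <- out$start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write interval calls as BED6
#'
#' Scores are given on a percent-like 0-100 scale (percent identity, or a
#' mean absolute skew multiplied by 100) and stored in the BED score field
#' as `round(score * 10)`, clamped to `[0, 1000]` with a warning.
#'
#' @param calls Data frame with columns `start`, `end` (0-based half-open),
#'   and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @param chrom Chromosome/sequence label for column 1.
#' @export
write_bed <- function(calls, path, chrom = "cluster") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (NROW(calls) == 0) return(invisible(NULL))
  if (any(calls$end <= calls$start)) stop("interval with end <= start")
  name <- if (is.null(calls$name)) sprintf("region_%d", seq_len(nrow(calls)))
          else calls$name
  score <- if (is.null(calls$score)) rep(0, nrow(calls)) else calls$score
  strand <- if (is.null(calls$strand)) rep("+", nrow(calls)) else calls$strand
  bed_score <- round(score * 10)
  if (any(bed_score < 0 | bed_score > 1000)) {
    warning("BED score(s) outside [0, 1000] clamped")
    bed_score <- pmin(pmax(bed_score, 0), 1000)
  }
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", chrom,
                     as.integer(calls$start), as.integer(calls$end),
                     name, as.integer(bed_score), strand), con)
  invisible(NULL)
}

#' Read a BED6 file written by [write_bed()]
#'
#' @param path Input path.
#' @return Data frame with `chrom`, `start`, `end`, `name`, `score`
#'   (rescaled back to the 0-100 scale), `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1),
             start = as.integer(vapply(parts, `[`, "", 2)),
             end = as.integer(vapply(parts, `[`, "", 3)),
             name = vapply(parts, `[`, "", 4),
             score = as.numeric(vapply(parts, `[`, "", 5)) / 10,
             strand = vapply(parts, `[`, "", 6),
             stringsAsFactors = FALSE)
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 significant digits; duplicate leaf
#' labels are rejected so the file round-trips unambiguously.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  ape::write.tree(tree, file = path, digits = 6)
  invisible(NULL)
}

#' Read a Newick tree
#'
#' @param path Input path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
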