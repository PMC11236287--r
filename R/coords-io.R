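#' @importFrom rtracklayer import
#' @importFrom utils write.table head
#' @importFrom stats setNames
NULL

# strip "#"-comment and blank lines, remembering original line numbers
.readDataLines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw) & !grepl("^(track|browser)\\b", raw)
  list(lines = raw[keep], lineno = which(keep))
}

#' Read a gene-family coordinate file in BED format
#'
#' BED coordinates (0-based half-open) are converted exactly to the 1-based
#' closed convention of GRanges. Column 4, when present, provides the gene
#' identifier; otherwise one is synthesized as `"<scaffold>:<start>-<end>"`
#' using the BED coordinates. Column 6, when present, provides the strand
#' (`.` is kept as unknown). Lines starting with `#`, `track` or `browser`
#' are ignored.
#'
#' @param path path to a BED3/BED4/BED6 file.
#' @param family family label attached to the records.
#' @return A [GeneFamily-class] in canonical (scaffold, start, end, gene_id)
#'   order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tgeneA", "chr1\t500\t600\tgeneB"), bed)
#' readFamilyBED(bed, "toy")
#' @export
readFamilyBED <- function(path, family) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  dat <- .readDataLines(path)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    where <- sprintf("%s line %d", path, dat$lineno[i])
    if (length(f) < 3L)
      stop("BED parse error at ", where, ": fewer than 3 tab-separated columns")
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e))
      stop("BED parse error at ", where, ": non-integer coordinates")
    if (s >= e)
      stop("BED parse error at ", where, ": start >= end")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- as.numeric(vapply(fields, `[`, "", 2L))
  end <- as.numeric(vapply(fields, `[`, "", 3L))
  ids <- vapply(fields, function(f)
    if (length(f) >= 4L && nzchar(f[4L])) f[4L] else NA_character_, "")
  ids <- ifelse(is.na(ids),
                sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end)),
                ids)
  std <- vapply(fields, function(f)
    if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "*", "")
  if (anyDuplicated(ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gr <- GRanges(chrom, IRanges::IRanges(start0 + 1, end), strand = std)
  names(gr) <- ids
  geneFamily(gr, family)
}

#' Read a gene-family coordinate file in GFF3 format
#'
#' Rows whose feature type (column 3) equals `featureType` are kept; their
#' 1-based closed coordinates are used as-is. The identifier is taken from
#' the attribute named by `idAttribute`. A gene annotated as several rows
#' with the same identifier (discontinuous annotation) is collapsed to the
#' minimal covering interval, with a warning: clustering operates on gene
#' loci, not exon structure.
#'
#' @param path path to a GFF3 file.
#' @param family family label.
#' @param featureType feature type to select (default `"gene"`).
#' @param idAttribute attribute key holding the gene identifier
#'   (default `"ID"`).
#' @return A [GeneFamily-class].
#' @export
readFamilyGFF3 <- function(path, family, featureType = "gene",
                           idAttribute = "ID") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  sel <- as.character(gr$type) == featureType
  if (!any(sel))
    stop(sprintf(
      "no '%s' rows in %s; feature types present: {%s}",
      featureType, path,
      paste(sort(unique(as.character(gr$type))), collapse = ", ")))
  gr <- gr[sel]
  attrs <- S4Vectors::mcols(gr)
  ids <- if (idAttribute %in% colnames(attrs))
    as.character(attrs[[idAttribute]]) else rep(NA_character_, length(gr))
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad) > 0L)
    stop(sprintf(
      "GFF3 rows without attribute '%s' in %s: %s", idAttribute, path,
      paste(sprintf("%s:%d-%d", as.character(seqnames(gr))[bad],
                    start(gr)[bad], end(gr)[bad]), collapse = ", ")))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    scafPerId <- split(as.character(seqnames(gr)), ids)
    multi <- names(Filter(function(s) length(unique(s)) > 1L, scafPerId))
    if (length(multi) > 0L)
      stop("gene id(s) annotated on more than one scaffold: ",
           paste(multi, collapse = ", "))
    warning("collapsing discontinuous annotation to minimal covering ",
            "interval for: ", paste(dup, collapse = ", "))
    parts <- split(seq_along(gr), ids)
    gr <- unlist(GenomicRanges::GRangesList(lapply(parts, function(i)
      GRanges(as.character(seqnames(gr))[i[1L]],
              IRanges::IRanges(min(start(gr)[i]), max(end(gr)[i])),
              strand = as.character(strand(gr))[i[1L]]))))
    names(gr) <- names(parts)
  } else {
    names(gr) <- ids
  }
  out <- GRanges(as.character(seqnames(gr)),
                 IRanges::IRanges(start(gr), end(gr)),
                 strand = as.character(strand(gr)))
  names(out) <- names(gr)
  geneFamily(out, family)
}

#' Write a GeneFamily as a BED6 file
#'
#' Emits the canonical sort order with 0-based half-open coordinates, score 0
#' and `.` for unknown strand, so that write -> read -> write is
#' byte-identical.
#'
#' @param fam a [GeneFamily-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFamilyBED <- function(fam, path) {
  stopifnot(is(fam, "GeneFamily"))
  gr <- familyRanges(fam)
  std <- as.character(strand(gr))
  std[std == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   names(gr), std)
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-gene summary table
#'
#' One row per family member with its clustered/singleton status. Coordinates
#' are written 1-based closed. Every gene of `fam` must appear exactly once
#' in `clusterSet`.
#'
#' @param fam a [GeneFamily-class].
#' @param clusterSet the [GeneClusterSet-class] computed from `fam`.
#' @param path output TSV path.
#' @return The table, invisibly, as written.
#' @export
writeGeneTable <- function(fam, clusterSet, path) {
  stopifnot(is(fam, "GeneFamily"), is(clusterSet, "GeneClusterSet"))
  ids <- geneIDs(fam)
  missing <- setdiff(ids, geneIDs(clusterSet))
  extra <- setdiff(geneIDs(clusterSet), ids)
  if (length(missing) > 0L || length(extra) > 0L)
    stop("gene table / cluster set mismatch; missing from clusters: {",
         paste(missing, collapse = ", "), "}; not in family: {",
         paste(extra, collapse = ", "), "}")
  gr <- familyRanges(fam)
  byGene <- clusterOf(clusterSet)[ids]
  sizes <- setNames(clusters(clusterSet)$n, clusters(clusterSet)$cluster_id)
  df <- data.frame(
    gene_id = ids,
    scaffold = as.character(seqnames(gr)),
    start = start(gr), end = end(gr),
    strand = as.character(strand(gr)),
    status = ifelse(is.na(byGene), "singleton", "clustered"),
    cluster_id = ifelse(is.na(byGene), "", byGene),
    cluster_size = ifelse(is.na(byGene), 1L, sizes[byGene]),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write the per-cluster summary table
#'
#' @param clusterSet a [GeneClusterSet-class].
#' @param path output TSV path.
#' @return The table, invisibly.
#' @export
writeClusterTable <- function(clusterSet, path) {
  stopifnot(is(clusterSet, "GeneClusterSet"))
  cl <- clusters(clusterSet)
  df <- data.frame(
    cluster_id = cl$cluster_id, scaffold = cl$scaffold, n = cl$n,
    first_start = cl$first_start, last_end = cl$last_end,
    span_bp = cl$span_bp, gap_span_bp = cl$gap_span_bp,
    max_len_CL = cl$max_len_CL,
    member_ids = vapply(cl$members, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
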