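#' @importFrom utils packageVersion
NULL

# rethrow any error from expr with a pipeline stage class, so callers (and
# the CLI) can distinguish input, consistency and external-tool failures
.rethrow <- function(expr, class, stage) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, c("gck_input_error", "gck_consistency_error",
                      "gck_external_error")))
      return()                                # already classified
    stop(errorCondition(
      sprintf("[%s] %s", stage, conditionMessage(e)),
      class = c(class, "gck_error")))
  })
}

.logStage <- function(stage, msg, verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Read a simple key = value run-configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values are returned as character; the caller coerces. CLI flags take
#' precedence over config-file values, which take precedence over defaults.
#'
#' @param path path to the config file.
#' @return A named list of character values.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  out <- lapply(kv, function(m) trimws(m[3L]))
  names(out) <- vapply(kv, function(m) trimws(m[2L]), "")
  out[nzchar(names(out))]
}

#' Run the full cluster-identification and analysis pipeline
#'
#' Orchestrates the whole workflow: coordinate parsing, cluster detection
#' under the gap threshold, the Poisson-null p-value, physical distance
#' matrices, optional evolutionary analysis (patristic distances, C_ST,
#' Mann-Whitney tests) when a tree or protein FASTA is supplied, optional
#' joint two-family analysis, figures, and a self-contained HTML report.
#' Tabular outputs are deterministic: two runs with identical inputs and
#' configuration are byte-identical.
#'
#' @param coords coordinate file of the focal family (BED or GFF3).
#' @param genomeSizeMb genome size in Mb (mandatory, as is `coords`).
#' @param outDir output directory; refused if non-empty unless `force`.
#' @param coordsB optional second family's coordinate file (joint mode).
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param familyLabel,familyLabelB family labels.
#' @param g,p gap threshold in bp / null probability; mutually exclusive
#'   (default g = 100 kb when neither is given). Applied to both families
#'   unless `gB` overrides the second family's threshold.
#' @param gB optional gap threshold for the second family.
#' @param tree optional Newick file with branch lengths; enables the
#'   evolutionary stage.
#' @param proteins optional protein FASTA; used with `engine` to infer a
#'   tree when `tree` is not given.
#' @param engine external phylogeny engine, see [runExternalPhylogeny()].
#' @param featureType,idAttribute GFF3 row selection, see [readFamilyGFF3()].
#' @param alternative sidedness of the Mann-Whitney test.
#' @param plots draw figures (disable for headless tabular runs).
#' @param force overwrite a non-empty output directory.
#' @param verbose one log line per stage.
#' @return Invisibly, a list (the report bundle): cluster sets, tables,
#'   file paths, figures and the materialized configuration.
#' @export
runPipeline <- function(coords, genomeSizeMb, outDir,
                        coordsB = NULL, format = "auto",
                        familyLabel = "family", familyLabelB = "family2",
                        g = NULL, p = NULL, gB = NULL,
                        tree = NULL, proteins = NULL,
                        engine = "mafft+fasttree",
                        featureType = "gene", idAttribute = "ID",
                        alternative = "two.sided",
                        plots = TRUE, force = FALSE, verbose = TRUE) {
  if (dir.exists(outDir) && length(dir(outDir, all.files = TRUE,
                                       no.. = TRUE)) > 0L && !force)
    stop(errorCondition(paste0("output directory not empty: ", outDir,
                               " (use force = TRUE to overwrite)"),
                        class = c("gck_input_error", "gck_error")))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  readFam <- function(path, label) {
    fmt <- if (format != "auto") format
           else if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
           else "gff3"
    if (fmt == "bed") readFamilyBED(path, label)
    else readFamilyGFF3(path, label, featureType, idAttribute)
  }

  fam <- .rethrow(readFam(coords, familyLabel), "gck_input_error", "coords")
  .logStage("coords", sprintf("read %d genes ('%s')", length(fam),
                              familyLabel), verbose)
  genome <- genomeSpec(genomeSizeMb,
                       unique(as.character(seqnames(familyRanges(fam)))))
  params <- .rethrow(clusterParams(genome, length(fam), g = g, p = p),
                     "gck_input_error", "params")
  cs <- findClusters(fam, params)
  .logStage("cluster", sprintf("%d cluster(s), %d singleton(s) at g = %s bp",
                               nrow(clusters(cs)), length(singletons(cs)),
                               format(gapThreshold(cs), big.mark = ",")),
            verbose)
  paths <- list(
    gene_table = file.path(outDir, "gene_table.tsv"),
    cluster_table = file.path(outDir, "cluster_table.tsv"),
    spectrum = file.path(outDir, "spectrum.tsv"),
    phys_matrix = file.path(outDir, "physical_distances.tsv"))
  .rethrow(writeGeneTable(fam, cs, paths$gene_table),
           "gck_consistency_error", "tables")
  writeClusterTable(cs, paths$cluster_table)
  spectrum <- clusterSizeSpectrum(cs)
  utils::write.table(spectrum, paths$spectrum, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  phys <- physicalDistances(fam)
  writeDistanceMatrix(phys, paths$phys_matrix)

  # ---- optional evolutionary stage -------------------------------------
  evol <- NULL; cst <- NULL; phyloTree <- NULL
  if (!is.null(tree) || !is.null(proteins)) {
    phyloTree <- if (!is.null(tree))
      .rethrow(readGeneTree(file = tree), "gck_input_error", "tree")
    else
      .rethrow(runExternalPhylogeny(proteins, engine,
                                    outDir = file.path(outDir, "phylo"),
                                    expectedIDs = geneIDs(fam)),
               "gck_external_error", "phylogeny")
    missingTips <- setdiff(geneIDs(fam), phyloTree$tip.label)
    if (length(missingTips) > 0L)
      stop(errorCondition(
        paste0("[tree] family members absent from the tree: ",
               paste(utils::head(missingTips, 10L), collapse = ", ")),
        class = c("gck_consistency_error", "gck_error")))
    evol <- patristicMatrix(phyloTree)
    cst <- computeCst(evol, cs, alternative = alternative)
    paths$evol_matrix <- file.path(outDir, "evolutionary_distances.tsv")
    paths$cst_table <- file.path(outDir, "cst_table.tsv")
    writeDistanceMatrix(evol[geneIDs(fam), geneIDs(fam)], paths$evol_matrix)
    writeCstTable(cst, paths$cst_table)
    .logStage("evolution", sprintf("C_ST computed for %d scope(s)",
                                   nrow(cst)), verbose)
  } else .logStage("evolution", "skipped (no tree or proteins)", verbose)

  # ---- optional joint two-family stage ---------------------------------
  joint <- NULL; famB <- NULL
  if (!is.null(coordsB)) {
    famB <- .rethrow(readFam(coordsB, familyLabelB), "gck_input_error",
                     "coordsB")
    paramsB <- if (is.null(gB)) NULL
               else clusterParams(genome, length(famB), g = gB)
    joint <- jointAnalysis(fam, famB, params, paramsB)
    paths$overlap_table <- file.path(outDir, "cluster_overlaps.tsv")
    writeOverlapTable(joint, paths$overlap_table)
    combined <- rbind(
      cbind(family = familyLabel,
            as.data.frame(utils::read.delim(paths$gene_table))),
      cbind(family = familyLabelB, {
        tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
        writeGeneTable(famB, familyB(joint) |> .stripPrefix(familyLabelB),
                       tmp)
        as.data.frame(utils::read.delim(tmp))
      }))
    paths$combined_gene_table <- file.path(outDir, "combined_gene_table.tsv")
    utils::write.table(combined, paths$combined_gene_table, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .logStage("joint", sprintf("%d cluster overlap(s)", nrow(overlaps(joint))),
              verbose)
  }

  # ---- figures ----------------------------------------------------------
  figures <- character(0)
  if (plots) {
    figures["Cluster size frequency spectrum"] <-
      saveFigure(plotSpectrum(spectrum), file.path(outDir, "spectrum"))[1L]
    scafTab <- table(cs@geneScaffolds)
    for (sc in names(scafTab)[scafTab >= 2L]) {
      fp <- saveFigure(function()
        plotDistanceHeatmap(phys, cs, evol = evol, scaffold = sc),
        file.path(outDir, paste0("heatmap_", sc)), width = 7, height = 7)
      figures[paste0("Distance heatmap - ", sc)] <- fp[1L]
    }
    if (!is.null(evol))
      figures["Physical vs evolutionary distances"] <-
        saveFigure(plotPhysVsEvol(phys, evol, cs),
                   file.path(outDir, "phys_vs_evol"))[1L]
    if (!is.null(joint)) {
      combFam <- .combineFamilies(fam, famB)
      physAB <- physicalDistances(combFam)
      scafB <- familyB(joint)@geneScaffolds
      bothScafs <- intersect(names(scafTab), unique(scafB))
      for (sc in bothScafs) {
        nAB <- sum(as.character(seqnames(familyRanges(combFam))) == sc)
        if (nAB < 2L) next
        fp <- saveFigure(function()
          plotDistanceHeatmap(physAB, familyA(joint), scaffold = sc,
                              clusters2 = familyB(joint)),
          file.path(outDir, paste0("joint_heatmap_", sc)),
          width = 7, height = 7)
        figures[paste0("Joint heatmap - ", sc)] <- fp[1L]
      }
    }
    .logStage("figures", sprintf("%d figure(s) written", length(figures)),
              verbose)
  }

  # ---- metadata + report -----------------------------------------------
  config <- list(
    coords = coords, coordsB = coordsB, genome_size_mb = genomeSizeMb,
    family_label = familyLabel, family_label_b =
      if (is.null(coordsB)) NULL else familyLabelB,
    g_bp = gapThreshold(cs), null_p_value = gapNullPValue(cs),
    g_bp_family_b = if (!is.null(joint)) gapThreshold(familyB(joint)) else NULL,
    tree = tree, proteins = proteins,
    feature_type = featureType, id_attribute = idAttribute,
    alternative = alternative,
    distance_definition = "intergenic gap (end-to-start, 0 for overlaps)",
    dc_pooling = "within-cluster pairs pooled across clusters",
    mwu_between_set = "all pairs not fully inside one cluster",
    tool_version = as.character(packageVersion("GeneClusterKit")))
  paths$metadata <- file.path(outDir, "run_metadata.json")
  jsonlite::write_json(Filter(Negate(is.null), config), paths$metadata,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tables <- list(
    "Cluster summary" = as.data.frame(utils::read.delim(paths$cluster_table)),
    "Gene summary" = as.data.frame(utils::read.delim(paths$gene_table)),
    "Cluster size spectrum" = spectrum)
  if (!is.null(cst)) tables[["C_ST by scope"]] <- cst
  if (!is.null(joint))
    tables[["Cluster overlaps (joint)"]] <- as.data.frame(overlaps(joint))
  rep_ <- renderHTMLReport(file.path(outDir, "report.html"),
                           sprintf("Gene family cluster report: %s",
                                   familyLabel),
                           params = config, tables = tables,
                           figures = figures)
  paths$report <- rep_$path
  .logStage("report", paths$report, verbose)
  invisible(list(family = fam, clusterSet = cs, spectrum = spectrum,
                 physicalDistances = phys, tree = phyloTree,
                 evolDistances = evol, cst = cst, joint = joint,
                 figures = figures, paths = paths, config = config,
                 reportOK = rep_$ok))
}

# rebuild a cluster set keyed by unprefixed gene ids (joint mode prefixes
# ids with the family label for disjointness)
.stripPrefix <- function(cs, label) {
  pre <- paste0(label, ":")
  strip <- function(x) sub(paste0("^", pre), "", x)
  cl <- clusters(cs)
  cl$members <- CharacterList(lapply(cl$members, strip))
  gs <- cs@geneScaffolds
  names(gs) <- strip(names(gs))
  new("GeneClusterSet", family = cs@family, genes = strip(cs@genes),
      geneScaffolds = gs, params = cs@params, clusters = cl,
      singletons = strip(cs@singletons))
}

# one family holding both gene sets (prefixed ids), for the joint heatmap
.combineFamilies <- function(famA, famB) {
  grA <- familyRanges(famA); grB <- familyRanges(famB)
  names(grA) <- paste(familyName(famA), names(grA), sep = ":")
  names(grB) <- paste(familyName(famB), names(grB), sep = ":")
  gr <- c(GRanges(as.character(seqnames(grA)),
                  IRanges::IRanges(start(grA), end(grA)),
                  strand = as.character(strand(grA))),
          GRanges(as.character(seqnames(grB)),
                  IRanges::IRanges(start(grB), end(grB)),
                  strand = as.character(strand(grB))))
  names(gr) <- c(names(grA), names(grB))
  geneFamily(gr, "joint")
}
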