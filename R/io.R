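#' @include utils.R AllClasses.R
NULL

MAG_FEATURES <- c("genome_size", "gene_count", "trna_count", "gc_content",
                  "coding_density")
FRACTION_COLUMNS <- c("completeness", "contamination", "gc_content",
                      "coding_density")

#' Read a MAG feature table
#'
#' Expects a TSV with header and at least the columns `mag_id`,
#' `completeness`, `contamination`, plus one or more genomic feature columns
#' (`genome_size`, `gene_count`, `trna_count`, `gc_content`,
#' `coding_density`). A `taxonomy` column in GTDB style
#' (`d__...;p__...;...;g__...`) is split into rank columns; alternatively
#' rank columns (`domain` .. `genus`) may be given directly. Fraction-typed
#' columns supplied on a percent scale (values > 1) are converted to
#' fractions with a warning.
#'
#' @param path TSV file path.
#' @return data.frame, one row per MAG, row order preserved.
#' @export
readMagTable <- function(path) {
  df <- readTsv(path)
  requireColumns(df, c("mag_id", "completeness", "contamination"), "MAG table")
  if (anyDuplicated(df$mag_id)) {
    pd_stop(sprintf("MAG table: duplicated mag_id '%s'",
                    df$mag_id[duplicated(df$mag_id)][1]),
            "phylodepth_integrity_error")
  }
  feat <- intersect(MAG_FEATURES, names(df))
  if (length(feat) == 0) {
    pd_stop("MAG table: needs at least one feature column", "phylodepth_schema_error")
  }
  for (col in c("completeness", "contamination", feat)) {
    df[[col]] <- checkNumericColumn(df[[col]], col, "MAG table")
  }
  for (col in intersect(FRACTION_COLUMNS, names(df))) {
    df[[col]] <- fractionize(df[[col]], col, "MAG table")
  }
  if (any(df$completeness <= 0, na.rm = TRUE)) {
    pd_stop("MAG table: completeness must be > 0", "phylodepth_integrity_error")
  }
  if (any(df$contamination >= 1, na.rm = TRUE)) {
    pd_stop("MAG table: contamination must be < 1", "phylodepth_integrity_error")
  }
  if ("taxonomy" %in% names(df) && !all(TAXONOMY_RANKS %in% names(df))) {
    df <- cbind(df, parseTaxonomyStrings(df$taxonomy))
  }
  df
}

# GTDB-style lineage strings -> rank columns; missing names flagged unassigned.
parseTaxonomyStrings <- function(x) {
  prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  out <- lapply(names(prefixes), function(rank) {
    pre <- prefixes[[rank]]
    vapply(strsplit(ifelse(is.na(x), "", x), ";"), function(parts) {
      parts <- trimws(parts)
      hit <- parts[startsWith(parts, pre)]
      val <- if (length(hit) > 0) sub(pre, "", hit[1], fixed = TRUE) else ""
      if (nzchar(val)) val else "unassigned"
    }, character(1))
  })
  names(out) <- names(prefixes)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' Expects TSV columns `sample_id`, `latitude`, `longitude`, `glacier_area`,
#' `distance_to_glacier`, `water_temperature`, `chlorophyll_a`. The glacier
#' index is recomputed from area and distance via [glacierIndex()] when not
#' supplied.
#'
#' @param path TSV file path.
#' @return data.frame, one row per sample, with a `glacier_index` column.
#' @export
readSampleTable <- function(path) {
  df <- readTsv(path)
  need <- c("sample_id", "latitude", "longitude", "glacier_area",
            "distance_to_glacier", "water_temperature", "chlorophyll_a")
  requireColumns(df, need, "sample table")
  if (anyDuplicated(df$sample_id)) {
    pd_stop("sample table: duplicated sample_id", "phylodepth_integrity_error")
  }
  for (col in setdiff(need, "sample_id")) {
    df[[col]] <- checkNumericColumn(df[[col]], col, "sample table")
  }
  if (any(abs(df$latitude) > 90, na.rm = TRUE) ||
      any(df$longitude <= -180 | df$longitude > 180, na.rm = TRUE)) {
    pd_stop("sample table: coordinates out of range", "phylodepth_integrity_error")
  }
  if (!"glacier_index" %in% names(df)) {
    df$glacier_index <- glacierIndex(df$glacier_area, df$distance_to_glacier)
  } else {
    df$glacier_index <- checkNumericColumn(df$glacier_index, "glacier_index",
                                           "sample table")
  }
  df
}

#' Read a MAG-by-sample abundance table
#'
#' First column `mag_id`, remaining columns one per sample, values
#' trimmed-mean coverages. When `recaPath` is supplied (TSV with columns
#' `sample_id`, `reca_coverage`), each sample column is divided by that
#' sample's recA coverage ([normalizeCoverage()]); otherwise values are taken
#' as already recA-normalized.
#'
#' @param path abundance TSV path.
#' @param recaPath optional per-sample recA coverage TSV path.
#' @return numeric matrix (MAG x sample).
#' @export
readAbundanceTable <- function(path, recaPath = NULL) {
  df <- readTsv(path)
  requireColumns(df, "mag_id", "abundance table")
  if (anyDuplicated(df$mag_id)) {
    pd_stop("abundance table: duplicated mag_id", "phylodepth_integrity_error")
  }
  if (ncol(df) < 2) {
    pd_stop("abundance table: no sample columns", "phylodepth_schema_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    pd_stop("abundance table: non-numeric or missing coverage value",
            "phylodepth_parse_error")
  }
  rownames(m) <- df$mag_id
  if (!is.null(recaPath)) {
    reca <- readTsv(recaPath)
    requireColumns(reca, c("sample_id", "reca_coverage"), "recA table")
    missing <- setdiff(colnames(m), reca$sample_id)
    if (length(missing) > 0) {
      pd_stop(sprintf("recA table: no coverage for sample(s) %s",
                      paste(missing, collapse = ", ")),
              "phylodepth_integrity_error")
    }
    rc <- reca$reca_coverage[match(colnames(m), reca$sample_id)]
    m <- vapply(seq_len(ncol(m)), function(j) {
      normalizeCoverage(m[, j], rc[j], sample = colnames(m)[j])
    }, numeric(nrow(m)))
    rownames(m) <- df$mag_id
    colnames(m) <- df_names <- names(df)[-1]
  }
  m
}

#' Read a MAG-by-KO copy-count table
#'
#' Rows are MAGs (`mag_id` column), remaining columns KO identifiers
#' (e.g. `K00003`) with non-negative integer copy counts.
#'
#' @param path TSV file path.
#' @return integer matrix (MAG x KO).
#' @export
readKoTable <- function(path) {
  df <- readTsv(path)
  requireColumns(df, "mag_id", "KO table")
  if (anyDuplicated(df$mag_id)) {
    pd_stop("KO table: duplicated mag_id", "phylodepth_integrity_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0)) {
    pd_stop("KO table: counts must be non-negative numbers",
            "phylodepth_parse_error")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$mag_id
  m
}

#' Read a rooted phylogenetic tree
#'
#' Reads a newick file, requiring uniquely labeled tips and non-negative
#' branch lengths.
#'
#' @param path newick file path.
#' @return an `ape::phylo` tree.
#' @export
readMagTree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) {
      pd_stop(sprintf("malformed newick: unbalanced ')' at character %d", i),
              "phylodepth_parse_error")
    }
  }
  if (depth != 0L) {
    pd_stop(sprintf("malformed newick: %d unclosed '(' at end of input", depth),
            "phylodepth_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    pd_stop("malformed newick: could not parse tree", "phylodepth_parse_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    pd_stop(sprintf("tree: duplicated tip label '%s'",
                    tree$tip.label[duplicated(tree$tip.label)][1]),
            "phylodepth_integrity_error")
  }
  if (any(!nzchar(tree$tip.label))) {
    pd_stop("tree: unlabeled tip", "phylodepth_integrity_error")
  }
  if (is.null(tree$edge.length)) {
    pd_stop("tree: branch lengths required", "phylodepth_integrity_error")
  }
  if (any(tree$edge.length < 0)) {
    pd_stop("tree: negative branch lengths rejected", "phylodepth_integrity_error")
  }
  tree
}

#' Align the five inputs into one validated MAGExperiment
#'
#' Intersects MAG ids across the MAG table, the abundance matrix, the tree
#' (and the KO table when given), and sample ids across the abundance matrix
#' and the sample table; prunes the tree to the shared tips; reports dropped
#' entities. Never imputes: entities absent from any input are dropped with a
#' message. Idempotent: aligning an already-aligned bundle changes nothing.
#'
#' @param mags data.frame from [readMagTable()].
#' @param abundance matrix from [readAbundanceTable()].
#' @param tree `phylo` from [readMagTree()].
#' @param samples data.frame from [readSampleTable()].
#' @param koCounts optional matrix from [readKoTable()].
#' @param presenceThreshold presence threshold (default 0.1).
#' @return A [MAGExperiment-class].
#' @export
alignInputs <- function(mags, abundance, tree, samples, koCounts = NULL,
                        presenceThreshold = 0.1) {
  idSets <- list(mag_table = mags$mag_id, abundance = rownames(abundance),
                 tree = tree$tip.label)
  if (!is.null(koCounts)) idSets$ko_table <- rownames(koCounts)
  sharedMags <- Reduce(intersect, idSets)
  sharedSamples <- intersect(colnames(abundance), samples$sample_id)
  if (length(sharedMags) == 0 || length(sharedSamples) == 0) {
    pd_stop(paste0("alignment error: empty intersection; id set sizes: ",
                   paste(sprintf("%s=%d", names(idSets), lengths(idSets)),
                         collapse = ", "),
                   sprintf(", samples(abundance)=%d, samples(table)=%d",
                           ncol(abundance), nrow(samples))),
            "phylodepth_alignment_error")
  }
  if (length(sharedMags) < 3 || length(sharedSamples) < 3) {
    pd_stop(sprintf("alignment error: only %d MAG(s) and %d sample(s) shared (need >= 3 each)",
                    length(sharedMags), length(sharedSamples)),
            "phylodepth_alignment_error")
  }
  for (nm in names(idSets)) {
    dropped <- setdiff(idSets[[nm]], sharedMags)
    if (length(dropped) > 0) {
      message(sprintf("alignInputs: dropping %d MAG(s) only present in %s",
                      length(dropped), nm))
    }
  }
  nsDrop <- (ncol(abundance) - length(sharedSamples)) +
    (nrow(samples) - length(sharedSamples))
  if (nsDrop > 0) {
    message(sprintf("alignInputs: dropping %d unmatched sample entr%s",
                    nsDrop, if (nsDrop == 1) "y" else "ies"))
  }
  # keep input row order of the MAG table for the shared set
  sharedMags <- mags$mag_id[mags$mag_id %in% sharedMags]
  sharedSamples <- colnames(abundance)[colnames(abundance) %in% sharedSamples]
  treeP <- ape::keep.tip(tree, sharedMags)
  magData <- mags[match(sharedMags, mags$mag_id), , drop = FALSE]
  rownames(magData) <- magData$mag_id
  sampleData <- samples[match(sharedSamples, samples$sample_id), , drop = FALSE]
  rownames(sampleData) <- sampleData$sample_id
  MAGExperiment(
    abundance = abundance[sharedMags, sharedSamples, drop = FALSE],
    magData = magData[, setdiff(names(magData), "mag_id"), drop = FALSE],
    sampleData = sampleData[, setdiff(names(sampleData), "sample_id"), drop = FALSE],
    tree = treeP,
    koCounts = if (is.null(koCounts)) NULL else
      koCounts[sharedMags, , drop = FALSE],
    presenceThreshold = presenceThreshold
  )
}

#' Write a MAGExperiment back to the five input files
#'
#' Inverse of the readers: writes `mag_features.tsv`, `abundance.tsv`,
#' `samples.tsv`, `ko_counts.tsv` and `tree.nwk` under `dir`.
#'
#' @param ex a [MAGExperiment-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
writeInputBundle <- function(ex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- as.data.frame(SummarizedExperiment::rowData(ex))
  magDf <- cbind(mag_id = rownames(ex), rd)
  cd <- as.data.frame(SummarizedExperiment::colData(ex))
  sampleDf <- cbind(sample_id = colnames(ex), cd)
  abDf <- cbind(mag_id = rownames(ex), as.data.frame(abundances(ex)))
  paths <- c(
    mags = file.path(dir, "mag_features.tsv"),
    abundance = file.path(dir, "abundance.tsv"),
    samples = file.path(dir, "samples.tsv"),
    ko = file.path(dir, "ko_counts.tsv"),
    tree = file.path(dir, "tree.nwk")
  )
  writeTsv(magDf, paths[["mags"]])
  writeTsv(abDf, paths[["abundance"]])
  writeTsv(sampleDf, paths[["samples"]])
  koDf <- cbind(mag_id = rownames(ex), as.data.frame(koCounts(ex)))
  writeTsv(koDf, paths[["ko"]])
  ape::write.tree(magTree(ex), paths[["tree"]], digits = 12)
  invisible(paths)
}
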