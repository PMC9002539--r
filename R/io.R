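#' @include AllClasses.R
NULL

#' Construct an AsvExperiment
#'
#' @param counts samples-by-ASVs matrix of non-negative integer read counts
#'   (row names = sample ids, column names = ASV ids). Note the transposition
#'   relative to the stored object: internally ASVs are rows, following the
#'   features-by-samples convention.
#' @param design data.frame of per-sample study design, one row per sample in
#'   \code{rownames(counts)} order or keyed by a \code{sample_id} column.
#'   Expected columns: \code{subject_id}, \code{taster_status} (NT/MT/ST),
#'   \code{timepoint} (pre/post), \code{age}, \code{gender} (F/M), \code{bmi}.
#' @param tree optional rooted \code{ape::phylo} whose tips include every ASV.
#' @return an [AsvExperiment-class] object.
#' @examples
#' cnt <- matrix(c(5L, 0L, 1L, 3L), 2, 2,
#'               dimnames = list(c("s1", "s2"), c("ASV_1", "ASV_2")))
#' des <- data.frame(sample_id = c("s1", "s2"), subject_id = c("A", "A"),
#'                   taster_status = "NT", timepoint = c("pre", "post"),
#'                   age = 21, gender = "F", bmi = 24)
#' AsvExperiment(cnt, des)
#' @export
AsvExperiment <- function(counts, design = NULL, tree = NULL) {
  counts <- validateCountMatrix(counts)
  if (is.null(design)) {
    design <- data.frame(row.names = rownames(counts))
  } else {
    design <- as.data.frame(design)
    if ("sample_id" %in% colnames(design)) {
      if (anyDuplicated(design$sample_id))
        stop("duplicate sample_id in design")
      rownames(design) <- design$sample_id
      design$sample_id <- NULL
    }
    missing <- setdiff(rownames(counts), rownames(design))
    if (length(missing))
      stop("samples without a design row: ", paste(missing, collapse = ", "))
    design <- design[rownames(counts), , drop = FALSE]
    .validateDesign(design)
  }
  if (!is.null(tree)) .checkTreeCovers(tree, colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)),
    colData = S4Vectors::DataFrame(design)
  )
  methods::new("AsvExperiment", se, tree = tree)
}

.validateDesign <- function(design) {
  if ("taster_status" %in% colnames(design)) {
    bad <- setdiff(unique(as.character(design$taster_status)), c("NT", "MT", "ST"))
    if (length(bad)) stop("invalid taster_status: ", paste(bad, collapse = ", "))
  }
  if ("timepoint" %in% colnames(design)) {
    bad <- setdiff(unique(as.character(design$timepoint)), c("pre", "post"))
    if (length(bad)) stop("invalid timepoint: ", paste(bad, collapse = ", "))
  }
  if ("gender" %in% colnames(design)) {
    bad <- setdiff(unique(as.character(design$gender)), c("F", "M"))
    if (length(bad)) stop("invalid gender: ", paste(bad, collapse = ", "))
  }
  if (all(c("subject_id", "timepoint") %in% colnames(design))) {
    if (anyDuplicated(paste(design$subject_id, design$timepoint)))
      stop("duplicate (subject_id, timepoint) in design")
  }
  invisible(design)
}

.checkTreeCovers <- function(tree, asvIds) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'")
  missing <- setdiff(asvIds, tree$tip.label)
  if (length(missing))
    stop("ASVs missing from tree: ", paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "")
  invisible(TRUE)
}

#' Validate a samples-by-ASVs count matrix
#'
#' @param counts numeric matrix; must be non-negative integers with unique,
#'   non-empty row (sample) and column (ASV) names, at least 2 x 2.
#' @return the matrix, storage mode integer.
#' @export
validateCountMatrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts need sample (row) and ASV (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids")
  if (any(!is.finite(counts))) stop("counts contain NA/NaN/Inf")
  if (any(counts < 0)) stop("negative count")
  if (any(counts != round(counts))) stop("non-integer count")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 samples and 2 ASVs")
  storage.mode(counts) <- "integer"
  counts
}

#' Accessors for AsvExperiment
#'
#' \code{asvCounts} returns the samples-by-ASVs count matrix (transposed from
#' internal storage), \code{sampleData} the design data.frame, and
#' \code{asvTree} the attached phylogeny (or NULL).
#'
#' @param x an [AsvExperiment-class].
#' @return see above.
#' @export
asvCounts <- function(x) {
  stopifnot(methods::is(x, "AsvExperiment"))
  t(SummarizedExperiment::assay(x, "counts"))
}

#' @rdname asvCounts
#' @export
sampleData <- function(x) {
  stopifnot(methods::is(x, "AsvExperiment"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @rdname asvCounts
#' @export
asvTree <- function(x) {
  stopifnot(methods::is(x, "AsvExperiment"))
  x@tree
}

setMethod("show", "AsvExperiment", function(object) {
  cat("AsvExperiment:", nrow(object), "ASVs x", ncol(object), "samples\n")
  cat("  reads/sample:", paste(range(colSums(SummarizedExperiment::assay(object))),
                               collapse = "-"), "\n")
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd)) cat("  design columns:", paste(colnames(cd), collapse = ", "), "\n")
  cat("  tree:", if (is.null(object@tree)) "none" else
      paste0(length(object@tree$tip.label), " tips"), "\n")
})

#' Read / write a count table (TSV)
#'
#' Tab-separated UTF-8 with a header row. Canonical orientation is samples as
#' rows (first column the sample id); \code{samplesAsRows = FALSE} transposes
#' on read for ASVs-as-rows files.
#'
#' @param path file path.
#' @param samplesAsRows orientation flag.
#' @return \code{readCountTable}: validated samples-by-ASVs integer matrix.
#' @export
readCountTable <- function(path, samplesAsRows = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in count table")
  rownames(m) <- ids
  if (!samplesAsRows) m <- t(m)
  validateCountMatrix(m)
}

#' @rdname readCountTable
#' @param counts samples-by-ASVs matrix.
#' @export
writeCountTable <- function(counts, path) {
  counts <- validateCountMatrix(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a study design table (TSV)
#'
#' Columns: sample_id, subject_id, taster_status, timepoint, age, gender, bmi
#' and optionally prop_rating_mm, nacl_rating_mm.
#'
#' @param path file path.
#' @return data.frame with rownames = sample_id.
#' @export
readDesign <- function(path) {
  # read as character first: a single-gender column of "F" would otherwise
  # be parsed as logical
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (numcol in intersect(c("age", "bmi", "prop_rating_mm", "nacl_rating_mm"),
                           colnames(df)))
    df[[numcol]] <- as.numeric(df[[numcol]])
  need <- c("sample_id", "subject_id", "taster_status", "timepoint")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) stop("design missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  rownames(df) <- df$sample_id
  .validateDesign(df)
  df
}

#' @rdname readDesign
#' @param design design data.frame (with sample_id column or rownames).
#' @export
writeDesign <- function(design, path) {
  if (!"sample_id" %in% colnames(design))
    design <- cbind(sample_id = rownames(design), design)
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table (TSV)
#'
#' Samples in rows (first column sample_id), variables in columns; values
#' real, missing allowed (empty or NA).
#'
#' @param path file path.
#' @return numeric data.frame with rownames = sample ids.
#' @export
readPhenotypeTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in phenotype table")
  vals <- df[, -1L, drop = FALSE]
  if (anyDuplicated(colnames(vals))) stop("duplicate variable names")
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) stop("non-numeric phenotype column: ", colnames(vals)[j])
    if (any(is.infinite(v))) stop("non-finite value in column: ", colnames(vals)[j])
  }
  rownames(vals) <- ids
  vals
}

#' @rdname readPhenotypeTable
#' @param pheno phenotype data.frame, rownames = sample ids.
#' @export
writePhenotypeTable <- function(pheno, path) {
  df <- data.frame(sample_id = rownames(pheno), pheno,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a Newick phylogeny
#'
#' @param path Newick file.
#' @param missingLengthZero if TRUE, missing branch lengths become 0; the
#'   default is to reject them, since the phylogenetic metrics need lengths.
#' @return rooted \code{ape::phylo}.
#' @export
readNewickTree <- function(path, missingLengthZero = FALSE) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("unparseable Newick file: ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (is.null(tr$edge.length)) {
    if (missingLengthZero) tr$edge.length <- rep(0, nrow(tr$edge))
    else stop("tree has no branch lengths")
  }
  if (anyNA(tr$edge.length)) {
    if (missingLengthZero) tr$edge.length[is.na(tr$edge.length)] <- 0
    else stop("tree has missing branch lengths")
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

#' @rdname readNewickTree
#' @param tree a \code{phylo}.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Write a distance matrix as square TSV
#'
#' @param d a \code{dist} or square matrix with sample ids.
#' @param path output file.
#' @export
writeDistanceMatrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
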