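#' Read a site-by-OTU count table from TSV
#'
#' Reads a tab-separated table with a header row and a label column and
#' validates it into the package's canonical orientation (sites as rows,
#' OTUs as columns, non-negative integer counts).
#'
#' @param path path to a TSV file whose first column holds row labels.
#' @param orientation `"sites-as-rows"` (default) or `"otus-as-rows"`; in
#'   the latter case the parsed table is transposed.
#' @param dropEmptySites drop all-zero site rows (with a warning) after
#'   parsing. Sites that never held a community (e.g. dried-out pools)
#'   carry no information for any downstream null model.
#' @return a validated site-by-OTU integer matrix.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' writeCommunityTable(m, tf)
#' identical(readCommunityTable(tf), m)
#' @export
readCommunityTable <- function(path,
                               orientation = c("sites-as-rows",
                                               "otus-as-rows"),
                               dropEmptySites = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!apply(df, 2, function(col) all(!is.na(suppressWarnings(
      as.numeric(col))))) == FALSE)
    stop("non-numeric cells in community table: ", path)
  }
  if (orientation == "otus-as-rows") m <- t(m)
  validateCommunityMatrix(m, dropEmptySites = dropEmptySites)
}

#' Validate a community count matrix
#'
#' Checks label uniqueness, integer non-negative counts, and (optionally)
#' removes all-zero site rows with a warning.
#'
#' @param m numeric matrix, sites as rows, with dimnames.
#' @param dropEmptySites remove all-zero rows (default TRUE).
#' @return the validated integer matrix.
#' @export
validateCommunityMatrix <- function(m, dropEmptySites = TRUE) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community matrix must carry site and OTU labels")
  if (anyDuplicated(rownames(m)))
    stop("duplicate site labels: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate OTU labels: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "invalid count at row '%s', column '%s' (must be a non-negative integer)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  if (dropEmptySites) {
    empty <- rowSums(m) == 0
    if (any(empty)) {
      warning("dropping all-zero site rows: ",
              paste(rownames(m)[empty], collapse = ", "))
      m <- m[!empty, , drop = FALSE]
    }
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a community matrix to TSV
#'
#' Deterministic writer: sites as rows, columns in the matrix's column
#' order, tab-separated with a leading label column.
#'
#' @param m site-by-OTU matrix.
#' @param path output path.
#' @export
writeCommunityTable <- function(m, path) {
  df <- data.frame(site = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contracts the
#' downstream phylogenetic nulls rely on: branch lengths present and
#' non-negative, tip labels unique, tree rooted.
#'
#' @param path newick file path.
#' @return an `ape::phylo`.
#' @export
readTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  validateTree(tr)
}

#' @rdname readTree
#' @param tree an `ape::phylo` to validate in place.
#' @export
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; patristic distances are undefined")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Patristic (tip-to-tip path-length) distances
#'
#' @param tree a rooted `phylo` with branch lengths (>= 2 tips).
#' @return symmetric numeric matrix of path lengths with a zero diagonal,
#'   labelled by tip.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' patristicDistances(tr)["A", "C"]  # 4
#' @export
patristicDistances <- function(tree) {
  validateTree(tree)
  if (length(tree$tip.label) < 2) stop("need at least 2 tips")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Read an environmental table or site coordinates from TSV
#'
#' `readEnvTable()` expects sites as rows (label column first) and numeric
#' variables; `readSiteCoords()` additionally requires columns `x` and `y`.
#'
#' @param path TSV path.
#' @return a data.frame with site row names.
#' @export
readEnvTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  if (anyDuplicated(rownames(df))) stop("duplicate site labels in ", path)
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(nonnum))
    stop("non-numeric environmental variables: ",
         paste(nonnum, collapse = ", "))
  if (anyNA(df)) stop("missing values in environmental table: ", path)
  df
}

#' @rdname readEnvTable
#' @export
readSiteCoords <- function(path) {
  df <- readEnvTable(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("coordinate table must have columns 'x' and 'y'")
  df[, c("x", "y")]
}

#' Read a BIOM v1 (JSON) table as a site-by-OTU matrix
#'
#' Optional reader requiring the `biomformat` package. BIOM stores
#' observations (OTUs) as rows; the result is transposed to the package's
#' sites-as-rows convention and validated.
#'
#' @param path BIOM v1 JSON file.
#' @inheritParams readCommunityTable
#' @export
readBiomTable <- function(path, dropEmptySites = TRUE) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  validateCommunityMatrix(m, dropEmptySites = dropEmptySites)
}
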