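## Case/control expression handling: log2 matrices -> per-gene and
## per-reaction linear fold changes -> the initial diseased flux target.

#' Construct an expression study
#'
#' @param matrix Numeric genes x samples matrix of log2-scale, already
#'   normalized expression values; rownames are gene symbols.
#' @param groups Character/factor of per-sample labels, \code{"control"} or
#'   \code{"patient"}, in column order (or named by sample).
#' @param study_id Identifier string.
#' @param collapse Collapse duplicate gene rows by their mean log2 value
#'   (default TRUE).
#' @return An object of class \code{expression_study}.
#' @export
expression_study <- function(matrix, groups, study_id = "study",
                             collapse = TRUE) {
  if (is.null(rownames(matrix))) stop("expression matrix needs gene rownames")
  if (!is.null(names(groups)) && !is.null(colnames(matrix))) {
    missing_lab <- setdiff(colnames(matrix), names(groups))
    if (length(missing_lab))
      stop("sample(s) without group label: ",
           paste(missing_lab, collapse = ", "))
    groups <- groups[colnames(matrix)]
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix))
    stop("groups length does not match sample count")
  bad <- setdiff(unique(groups), c("control", "patient"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(matrix)) stop("expression values must be numeric")
  if (anyNA(matrix)) stop("expression matrix contains non-numeric cells")
  if (collapse && anyDuplicated(rownames(matrix))) {
    sums <- rowsum(matrix, group = rownames(matrix))  # rows sorted by gene
    counts <- as.vector(table(rownames(matrix))[rownames(sums)])
    matrix <- sums / counts
  }
  structure(list(matrix = matrix, gene_ids = rownames(matrix),
                 groups = groups, study_id = study_id),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study '", x$study_id, "': ", nrow(x$matrix), " genes, ",
      sum(x$groups == "control"), " control / ",
      sum(x$groups == "patient"), " patient samples\n", sep = "")
  invisible(x)
}

#' Load an expression study from tab-delimited files
#'
#' The matrix file holds one gene per row (first column gene symbol, header
#' row of sample ids, log2-normalized values); the group assignment is a
#' two-column sample/group table or a named vector.  Duplicate gene rows
#' (multiple probes) are collapsed by their mean log2 value.
#'
#' @param path Path to the matrix file.
#' @param groups Either the path of a two-column (sample, group) file or a
#'   named character vector.
#' @param study_id Identifier (defaults to the file name).
#' @return An \code{expression_study}.
#' @export
load_expression <- function(path, groups,
                            study_id = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in expression matrix")
  rownames(mat) <- genes
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gt <- utils::read.delim(groups, stringsAsFactors = FALSE)
    groups <- stats::setNames(as.character(gt[[2]]), as.character(gt[[1]]))
  }
  expression_study(mat, groups, study_id = study_id)
}

#' Per-gene linear fold changes (patient vs control)
#'
#' \code{fc(g) = 2^(mean(log2 patient) - mean(log2 control))}; adding a
#' constant to all log2 values (a global normalization shift) leaves the
#' fold changes unchanged, and swapping the group labels maps each fold
#' change to its reciprocal.
#'
#' @param study An \code{expression_study}.
#' @return Named numeric vector of linear-scale fold changes (> 0).
#' @export
gene_fold_changes <- function(study) {
  ctrl <- study$groups == "control"
  pat <- study$groups == "patient"
  if (sum(ctrl) < 1L || sum(pat) < 1L)
    stop("each group needs at least one sample")
  delta <- rowMeans(study$matrix[, pat, drop = FALSE]) -
    rowMeans(study$matrix[, ctrl, drop = FALSE])
  2^delta
}

#' Per-reaction fold changes from per-gene fold changes
#'
#' Each reaction's fold change is the arithmetic mean of the linear fold
#' changes of its associated genes present in the study (matched
#' case-insensitively); genes absent from the study are skipped, and
#' reactions with no matched genes get fold change 1 with coverage 0.
#'
#' @param gene_fc Named numeric vector of linear gene fold changes.
#' @param net A \code{metabolic_network} with gene associations.
#' @return A \code{fold_change_map}: list with \code{gene_fc},
#'   \code{reaction_fc}, \code{coverage} (contributing gene counts) and
#'   \code{unmatched} (model genes absent from the study).
#' @export
reaction_fold_changes <- function(gene_fc, net) {
  if (any(gene_fc <= 0)) stop("fold changes must be positive")
  lookup <- stats::setNames(as.numeric(gene_fc), toupper(names(gene_fc)))
  rx <- net$reactions
  fc <- rep(1, nrow(rx))
  cov <- integer(nrow(rx))
  unmatched <- character(0)
  for (i in seq_len(nrow(rx))) {
    genes <- toupper(rx$genes[[i]])
    present <- genes %in% names(lookup)
    unmatched <- c(unmatched, rx$genes[[i]][!present])
    if (any(present)) {
      fc[i] <- mean(lookup[genes[present]])
      cov[i] <- sum(present)
    }
  }
  structure(list(gene_fc = gene_fc,
                 reaction_fc = stats::setNames(fc, rx$id),
                 coverage = stats::setNames(cov, rx$id),
                 unmatched = unique(unmatched)),
            class = "fold_change_map")
}

#' @export
print.fold_change_map <- function(x, ...) {
  cat("fold_change_map:", length(x$reaction_fc), "reactions,",
      sum(x$coverage > 0), "with gene evidence;",
      length(x$unmatched), "model genes unmatched\n")
  invisible(x)
}

#' Initial (rough) diseased flux estimate
#'
#' Per-reaction product of the healthy flux and the expression fold
#' change: the target vector of the least-squares stage.
#'
#' @param healthy Healthy \code{flux_distribution} (or named flux vector).
#' @param fcs A \code{fold_change_map} (or named fold-change vector).
#' @return Named numeric target vector \code{v0}.
#' @export
initial_flux_estimate <- function(healthy, fcs) {
  hv <- if (inherits(healthy, "flux_distribution")) healthy$values else
    healthy
  fc <- if (inherits(fcs, "fold_change_map")) fcs$reaction_fc else fcs
  if (!setequal(names(hv), names(fc)))
    stop("healthy fluxes and fold changes cover different reactions")
  hv * fc[names(hv)]
}

#' Export a fold-change map as the pathway-visualization table
#'
#' @param fcs A \code{fold_change_map}.
#' @param net The network (for gene lists).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fold_changes <- function(fcs, net, path) {
  tab <- data.frame(
    reaction_id = names(fcs$reaction_fc),
    fold_change = unname(fcs$reaction_fc),
    n_genes = unname(fcs$coverage),
    gene_list = vapply(net$reactions$genes, paste, character(1),
                       collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
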