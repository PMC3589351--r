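#' Gene/marker-by-sample omics matrix with group labels
#'
#' The universal input container: a numeric matrix whose rows are features
#' (genes, methylation probes or copy-number markers) and whose columns are
#' samples, together with a cancer/normal group factor aligned to the columns
#' and a modality tag.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param groups character or factor of length `ncol(values)` with levels
#'   `"cancer"` and `"normal"`.
#' @param modality one of `"expression"`, `"methylation"`, `"cna"`.
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `groups` (factor) and `modality`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' om <- omics_matrix(m, c("cancer", "cancer", "cancer", "normal", "normal"),
#'                    "expression")
#' @export
omics_matrix <- function(values, groups, modality = c("expression", "methylation", "cna")) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("`groups` must have one entry per sample column")
  bad <- setdiff(unique(groups), c("cancer", "normal"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  structure(
    list(values = values,
         groups = factor(groups, levels = c("cancer", "normal")),
         modality = modality),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d features x %d samples (%d cancer, %d normal)\n",
              x$modality, nrow(x$values), ncol(x$values),
              sum(x$groups == "cancer"), sum(x$groups == "normal")))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

cancer_cols <- function(om) om$values[, om$groups == "cancer", drop = FALSE]
normal_cols <- function(om) om$values[, om$groups == "normal", drop = FALSE]

#' Write / read an omics matrix as TSV
#'
#' On-disk format: first column holds the feature id (header `feature`), the
#' remaining columns are samples. Group labels travel in a separate
#' two-column TSV (`sample`, `group`).
#'
#' @param om an [omics_matrix()].
#' @param matrix_path,labels_path file paths for the value matrix and the
#'   group-label table.
#' @return `write_omics_tsv()` returns the paths invisibly;
#'   `read_omics_tsv()` returns an [omics_matrix()].
#' @export
write_omics_tsv <- function(om, matrix_path, labels_path) {
  df <- data.frame(feature = rownames(om$values), om$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample = colnames(om$values), group = as.character(om$groups))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, labels_path))
}

#' @rdname write_omics_tsv
#' @param modality modality tag for the object read back.
#' @export
read_omics_tsv <- function(matrix_path, labels_path,
                           modality = c("expression", "methylation", "cna")) {
  modality <- match.arg(modality)
  df <- utils::read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  groups <- lab$group[match(colnames(vals), lab$sample)]
  if (anyNA(groups)) stop("labels file is missing some samples")
  omics_matrix(vals, groups, modality)
}

#' Read per-sample copy-number segments and rasterize to markers
#'
#' SEG-like TSV with columns `sample`, `chrom`, `start`, `end`, `log2ratio`;
#' coordinates are 1-based inclusive on disk and converted to 0-based
#' half-open internally. Each chromosome is divided into `marker_spacing`-bp
#' bins ("markers"); a marker takes the log2 ratio of the segment covering
#' its midpoint (0 where no segment covers it).
#'
#' @param seg_path path to the SEG-like TSV.
#' @param groups named character vector or two-column data frame mapping
#'   sample to group.
#' @param marker_spacing bin width in bp.
#' @return An [omics_matrix()] of modality `"cna"` with markers named
#'   `<chrom>:<bin>` plus a `marker_map` attribute (marker, chrom, start, end;
#'   0-based half-open).
#' @export
read_seg_tsv <- function(seg_path, groups, marker_spacing = 1e5) {
  seg <- utils::read.delim(seg_path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "log2ratio")
  if (!all(need %in% names(seg)))
    stop("SEG file must have columns: ", paste(need, collapse = ", "))
  # 1-based inclusive -> 0-based half-open
  seg$start0 <- seg$start - 1L
  seg$end0 <- seg$end
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups[[2]]), groups[[1]])
  samples <- sort(unique(seg$sample))
  marker_rows <- list()
  per_chrom <- split(seg, seg$chrom)
  for (chrom in names(per_chrom)) {
    s <- per_chrom[[chrom]]
    n_bins <- ceiling(max(s$end0) / marker_spacing)
    marker_rows[[chrom]] <- data.frame(
      marker = sprintf("%s:%d", chrom, seq_len(n_bins)),
      chrom = chrom,
      start = (seq_len(n_bins) - 1L) * marker_spacing,
      end = seq_len(n_bins) * marker_spacing,
      stringsAsFactors = FALSE
    )
  }
  map <- do.call(rbind, marker_rows)
  rownames(map) <- NULL
  vals <- matrix(0, nrow(map), length(samples),
                 dimnames = list(map$marker, samples))
  mid <- (map$start + map$end) / 2
  for (i in seq_len(nrow(seg))) {
    hit <- map$chrom == seg$chrom[i] & mid >= seg$start0[i] & mid < seg$end0[i]
    vals[hit, seg$sample[i]] <- seg$log2ratio[i]
  }
  om <- omics_matrix(vals, unname(groups[samples]), "cna")
  attr(om, "marker_map") <- map
  om
}
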