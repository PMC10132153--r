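#' Feature-by-sample abundance table with sample metadata
#'
#' The central container for one data layer (proteomics intensities or
#' total/free/monosome/polysome RNA abundance): a nonnegative numeric matrix
#' with features in rows and samples in columns, plus per-sample metadata
#' giving the layer, the condition (\code{control}/\code{treated}) and the
#' experimental unit (e.g. cell line) each column belongs to.
#'
#' @param values numeric matrix, features x samples, with unique non-empty
#'   row and column names. Values must be nonnegative; \code{NA} is allowed
#'   (proteomics dropouts).
#' @param metadata data.frame with columns \code{sample}, \code{layer},
#'   \code{condition}, \code{unit}; one row per sample column of
#'   \code{values}. \code{layer} must be one of \code{protein}, \code{total},
#'   \code{free}, \code{monosome}, \code{polysome}; \code{condition} one of
#'   \code{control}, \code{treated}.
#' @return an object of class \code{abundance_table}: a list with elements
#'   \code{values} and \code{metadata}.
#' @export
abundance_table <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || anyNA(fid) || any(fid == ""))
    stop("'values' must have feature ids as row names")
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    stop("'values' must have sample ids as column names")
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  if (any(values < 0, na.rm = TRUE))
    stop("abundance values must be nonnegative")
  if (!is.data.frame(metadata))
    stop("'metadata' must be a data.frame")
  need <- c("sample", "layer", "condition", "unit")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  metadata <- metadata[, need, drop = FALSE]
  metadata[] <- lapply(metadata, as.character)
  if (anyDuplicated(metadata$sample))
    stop("duplicate sample in metadata: ",
         metadata$sample[duplicated(metadata$sample)][1L])
  orphan <- setdiff(sid, metadata$sample)
  if (length(orphan))
    stop("sample present in matrix but absent from metadata: ", orphan[1L])
  metadata <- metadata[match(sid, metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  bad_layer <- setdiff(unique(metadata$layer),
                       c("protein", "total", "free", "monosome", "polysome"))
  if (length(bad_layer))
    stop("unknown layer: ", bad_layer[1L])
  bad_cond <- setdiff(unique(metadata$condition), c("control", "treated"))
  if (length(bad_cond))
    stop("unknown condition (must be control/treated): ", bad_cond[1L])
  structure(list(values = values, metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples (layer %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$metadata$layer), collapse = "/")))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table to the samples of one layer and condition
#'
#' @param x abundance_table
#' @param layer,condition optional filters; \code{NULL} keeps all
#' @return abundance_table restricted to the matching sample columns
#' @export
subset_samples <- function(x, layer = NULL, condition = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  keep <- rep(TRUE, nrow(x$metadata))
  if (!is.null(layer)) keep <- keep & x$metadata$layer %in% layer
  if (!is.null(condition)) keep <- keep & x$metadata$condition %in% condition
  abundance_table(x$values[, keep, drop = FALSE],
                  x$metadata[keep, , drop = FALSE])
}

#' Read an abundance table and its sample metadata from tab-delimited text
#'
#' Lines beginning with \code{#} are ignored in both files. The abundance
#' file has a header of sample ids and feature ids in the first column; the
#' metadata file has columns sample/layer/condition/unit.
#'
#' @param path abundance matrix file
#' @param metadata_path sample metadata file
#' @return validated \code{abundance_table}
#' @export
read_abundance <- function(path, metadata_path) {
  raw <- read_tsv(path)
  if (ncol(raw) < 2L) stop("abundance file needs a feature column and at least one sample")
  fid <- as.character(raw[[1L]])
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  mat <- raw[, -1L, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("malformed numeric cell at row %d, column '%s': '%s'",
                     bad[1L], names(mat)[j], v[bad[1L]]))
      mat[[j]] <- vn
    }
  }
  values <- as.matrix(mat)
  rownames(values) <- fid
  metadata <- read_tsv(metadata_path)
  abundance_table(values, metadata)
}

#' Write an abundance table (matrix + metadata) as tab-delimited text
#'
#' @param x abundance_table
#' @param path output file for the matrix
#' @param metadata_path output file for the sample metadata
#' @param seed,config optional provenance recorded in the '#' header
#' @return invisibly, \code{path}
#' @export
write_abundance <- function(x, path, metadata_path, seed = NULL,
                            config = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  hdr <- rs_header(seed = seed, config = config)
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, header = hdr)
  write_tsv(x$metadata, metadata_path, header = hdr)
  invisible(path)
}

# Replicate values of one feature for one condition, ordered by unit id so
# that paired tests line up across conditions.
replicates <- function(x, feature, condition) {
  sel <- x$metadata$condition == condition
  md <- x$metadata[sel, , drop = FALSE]
  v <- x$values[feature, sel]
  v[order(md$unit)]
}
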