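# File formats: grayordinate activation tables (TSV), laterality results
# (TSV), connectome matrices (CSV + JSON sidecar), shape metric tables (TSV),
# and JSON run manifests. All tabular output is UTF-8, tab-separated, "NA"
# for missing, floats at 10 significant digits.

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a grayordinate activation table
#'
#' Expects a TSV with header `subject_id  grayordinate_id  hemisphere  roi  z`;
#' `hemisphere` must be `left` or `right`, z finite, and (subject,
#' grayordinate) pairs unique. Errors name the offending line.
#'
#' @param path file path.
#' @return validated long-format data frame (see [run_laterality()]).
#' @export
read_grayordinate_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "grayordinate_id", "hemisphere", "roi", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(df$hemisphere %in% c("left", "right")))
  if (length(bad))
    stop(path, ": bad hemisphere token at line ", bad[1L] + 1L,
         " (must be 'left' or 'right')")
  bad <- which(!is.finite(df$z))
  if (length(bad))
    stop(path, ": non-finite z at line ", bad[1L] + 1L)
  key <- paste(df$subject_id, df$grayordinate_id)
  bad <- which(duplicated(key))
  if (length(bad))
    stop(path, ": duplicate (subject_id, grayordinate_id) at line ", bad[1L] + 1L)
  df$subject_id <- as.character(df$subject_id)
  df$roi <- as.character(df$roi)
  df
}

#' @rdname read_grayordinate_table
#' @param maps grayordinate data frame to write.
#' @export
write_grayordinate_table <- function(maps, path) {
  validate_gray_map(maps)
  write_tsv(maps[, c("subject_id", "grayordinate_id", "hemisphere", "roi", "z")],
            path)
}

#' Write / read a per-subject laterality table
#'
#' TSV columns: `subject_id`, `family`, `L`, `R`, `LQ`, `dominance`
#' (and `flag_negative` when present).
#'
#' @param results data frame from [run_laterality()].
#' @param path file path.
#' @return the path (write) or the data frame (read).
#' @export
write_laterality_table <- function(results, path) write_tsv(results, path)

#' @rdname write_laterality_table
#' @export
read_laterality_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "family", "L", "R", "LQ", "dominance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a local connectome matrix with sidecar
#'
#' The QA matrix goes to CSV (rows = subjects with a `subject_id` column,
#' remaining columns = segment ids); segment geometry (position, orientation,
#' length, neighbor indices) and per-subject covariates go to a JSON sidecar.
#'
#' @param matrix a [local_connectome()].
#' @param covariates covariate data frame (subject_id, age, sex, handedness,
#'   lq).
#' @param path_matrix CSV path.
#' @param path_sidecar JSON path.
#' @return invisibly, the two paths.
#' @export
write_connectome_matrix <- function(matrix, covariates, path_matrix, path_sidecar) {
  stopifnot(inherits(matrix, "local_connectome"))
  qa <- matrix$qa
  df <- data.frame(subject_id = rownames(qa), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(qa))
  utils::write.table(df, path_matrix, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  seg <- matrix$segments
  sidecar <- list(
    segments = lapply(seq_len(nrow(seg)), function(i) list(
      id = seg$id[i],
      position = c(seg$x[i], seg$y[i], seg$z[i]),
      orientation = c(seg$ox[i], seg$oy[i], seg$oz[i]),
      length_mm = seg$length_mm[i],
      neighbors = as.integer(seg$neighbors[[i]]))),
    covariates = covariates)
  jsonlite::write_json(sidecar, path_sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path_matrix, path_sidecar))
}

#' Read a local connectome matrix with sidecar
#'
#' Cross-validates the CSV against the JSON sidecar: segment ids must match
#' the matrix columns and the adjacency must be symmetric.
#'
#' @param path_matrix CSV path (see [write_connectome_matrix()]).
#' @param path_sidecar JSON sidecar path.
#' @return list with `matrix` (a [local_connectome()]) and `covariates`.
#' @export
read_connectome_matrix <- function(path_matrix, path_sidecar) {
  df <- utils::read.csv(path_matrix, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stop(path_matrix, ": missing subject_id column")
  qa <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(qa) <- df$subject_id
  side <- jsonlite::read_json(path_sidecar, simplifyVector = FALSE)
  segs <- side$segments
  ids <- vapply(segs, function(s) s$id, "")
  if (!identical(ids, colnames(qa)))
    stop("segment ids in sidecar do not match matrix columns")
  segments <- data.frame(
    id = ids,
    x = vapply(segs, function(s) as.numeric(s$position[[1]]), 0.0),
    y = vapply(segs, function(s) as.numeric(s$position[[2]]), 0.0),
    z = vapply(segs, function(s) as.numeric(s$position[[3]]), 0.0),
    ox = vapply(segs, function(s) as.numeric(s$orientation[[1]]), 0.0),
    oy = vapply(segs, function(s) as.numeric(s$orientation[[2]]), 0.0),
    oz = vapply(segs, function(s) as.numeric(s$orientation[[3]]), 0.0),
    length_mm = vapply(segs, function(s) as.numeric(s$length_mm), 0.0),
    stringsAsFactors = FALSE)
  segments$neighbors <- I(lapply(segs, function(s)
    as.integer(unlist(s$neighbors))))
  covs <- side$covariates
  covariates <- data.frame(
    subject_id = vapply(covs, function(s) s$subject_id, ""),
    age = vapply(covs, function(s) as.numeric(s$age), 0.0),
    sex = vapply(covs, function(s) as.numeric(s$sex), 0.0),
    handedness = vapply(covs, function(s) as.numeric(s$handedness), 0.0),
    lq = vapply(covs, function(s) as.numeric(s$lq), 0.0),
    stringsAsFactors = FALSE)
  if (!identical(covariates$subject_id, rownames(qa)))
    stop("covariate subject ids do not match matrix rows")
  list(matrix = local_connectome(qa, segments), covariates = covariates)
}

#' Write a JSON run manifest
#'
#' Records the package version, the full configuration, the seed, and MD5
#' hashes of the input files, so a run is reproducible from the manifest
#' alone. No timestamps are written: reruns with the same seed produce
#' byte-identical manifests.
#'
#' @param path output JSON path.
#' @param config named list of parameters.
#' @param inputs character vector of input file paths to hash (optional).
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(0)) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else setNames(list(), character(0))
  manifest <- list(
    package = "latconn",
    version = as.character(utils::packageVersion("latconn")),
    config = config,
    input_md5 = hashes)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
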