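#' Write / read a trajectory as CSV plus a JSON sidecar
#'
#' The CSV has one frame per row with columns
#' `time,cf3_x,cf3_y[,cf3_z],o1_x,o1_y[,o1_z]`; the sidecar
#' (`<path>.json`) records seed, config hash and bond length. Full
#' precision (17 significant digits) is written so the round trip is exact.
#'
#' @param trajectory A `trajectory`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  d <- ncol(trajectory$cf3)
  ax <- c("x", "y", "z")[seq_len(d)]
  df <- data.frame(time = trajectory$times, trajectory$cf3, trajectory$o1)
  names(df) <- c("time", paste0("cf3_", ax), paste0("o1_", ax))
  write_csv_full(df, path)
  jsonlite::write_json(
    list(schema_version = 1L, seed = trajectory$seed,
         config_hash = trajectory$config_hash,
         bond_length = trajectory$bond_length),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  meta <- read_sidecar(path)
  df <- utils::read.csv(path)
  ax_cols <- grep("^cf3_", names(df))
  structure(list(times = df$time,
                 cf3 = as.matrix(df[, ax_cols, drop = FALSE]),
                 o1 = as.matrix(df[, grep("^o1_", names(df)), drop = FALSE]),
                 bond_length = meta$bond_length, seed = meta$seed,
                 config_hash = meta$config_hash),
            class = "trajectory")
}

#' Write / read an assay dataset as CSV plus a JSON sidecar
#'
#' CSV columns `x,y`; the sidecar records kind, noise level, seed and the
#' generating parameters.
#'
#' @param dataset An `assay_dataset`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_assay <- function(dataset, path) {
  write_csv_full(data.frame(x = dataset$x, y = dataset$y), path)
  jsonlite::write_json(
    list(schema_version = 1L, kind = dataset$kind,
         noise_sd = dataset$noise_sd, seed = dataset$seed,
         true_params = dataset$true_params),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_assay
#' @export
read_assay <- function(path) {
  meta <- read_sidecar(path)
  df <- utils::read.csv(path)
  assay_dataset(meta$kind, df$x, df$y, meta$noise_sd, meta$seed,
                meta$true_params)
}

#' Write / read a metadynamics hill list
#'
#' CSV columns `time,center,height,width`, written at full precision so a
#' reload reproduces the bias bit-exactly.
#'
#' @param bias A `bias_state`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(bias, path) {
  write_csv_full(bias$hills[, c("time", "center", "height", "width")], path)
  invisible(path)
}

#' @rdname write_hills
#' @param anchor_set,params Bias metadata to attach to the reloaded state
#'   (hills files carry only the hills themselves).
#' @export
read_hills <- function(path, anchor_set = 0, params = hill_params()) {
  b <- bias_state(anchor_set, params)
  b$hills <- utils::read.csv(path)
  b
}

#' Write a free-energy profile as CSV
#'
#' Columns `cv,free_energy`.
#'
#' @param profile A `free_energy_profile`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write_csv_full(data.frame(cv = profile$grid, free_energy = profile$f), path)
  invisible(path)
}

#' Write / read a fingerprint matrix as TSV
#'
#' First column the snapshot id, remaining columns one `residue:type`
#' boolean each.
#'
#' @param matrix A `fingerprint_matrix`.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(matrix, path) {
  type <- attr(matrix, "interaction_type")
  df <- data.frame(snapshot = seq_len(nrow(matrix)),
                   as.data.frame(unclass(matrix) * 1L))
  names(df)[-1] <- paste0(colnames(matrix), ":", type)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @param ligand_id Ligand label for the reloaded matrix.
#' @export
read_fingerprints <- function(path, ligand_id = "ligand") {
  df <- utils::read.delim(path, check.names = FALSE)
  bits <- as.matrix(df[, -1, drop = FALSE]) == 1
  labels <- sub(":[^:]*$", "", colnames(bits))
  type <- sub("^.*:", "", colnames(df)[2])
  colnames(bits) <- labels
  fingerprint_matrix(bits, ligand_id = ligand_id, interaction_type = type)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar file: expected ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L)
    stop("schema-version mismatch in ", sp)
  meta
}

# full-precision CSV so numeric round trips are exact
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
}
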