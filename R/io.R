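# CSV and YAML input/output. Dialect is fixed: UTF-8, comma-separated,
# header row required, '.' decimal point.

.read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("%s: unreadable CSV (%s)", path,
                                conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L)
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  df
}

.require_cols <- function(df, cols, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.bad_rows <- function(cond, path, what) {
  if (any(cond, na.rm = TRUE) || anyNA(cond)) {
    rows <- which(cond | is.na(cond))
    stop(sprintf("%s: %s (rows %s)", path, what,
                 paste(utils::head(rows, 10), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a plate-observation table
#'
#' Expected columns: `sample_id`, `dilution_exponent`, `plated_volume_ul`,
#' `selective` (0/1), `colony_count`.
#'
#' @param path Path to `plates.csv`.
#' @return Validated data frame.
#' @export
read_plates <- function(path) {
  df <- .read_csv_strict(path)
  .require_cols(df, c("sample_id", "dilution_exponent", "plated_volume_ul",
                      "selective", "colony_count"), path)
  .bad_rows(!(df$dilution_exponent >= 0 &
                df$dilution_exponent == floor(df$dilution_exponent)),
            path, "dilution_exponent must be a non-negative integer")
  .bad_rows(!(df$plated_volume_ul > 0), path,
            "plated_volume_ul must be positive")
  .bad_rows(!(df$colony_count >= 0 & df$colony_count == floor(df$colony_count)),
            path, "colony_count must be a non-negative integer")
  .bad_rows(!(df$selective %in% c(0, 1, TRUE, FALSE)), path,
            "selective must be 0/1")
  df$selective <- as.integer(as.logical(df$selective))
  df
}

#' Read an assay-sample table
#'
#' Expected columns: `sample_id`, `assay_type` (`monoculture`/`mixture`),
#' `strain_i`, `strain_j` (empty for monocultures), `initial_cells_total`,
#' `initial_fraction_i`, `resuspension_volume_ul`, `replicate_id`.
#'
#' @param path Path to `samples.csv`.
#' @return Validated data frame.
#' @export
read_samples <- function(path) {
  df <- .read_csv_strict(path)
  .require_cols(df, c("sample_id", "assay_type", "strain_i", "strain_j",
                      "initial_cells_total", "initial_fraction_i",
                      "resuspension_volume_ul", "replicate_id"), path)
  df$strain_j[!is.na(df$strain_j) & df$strain_j == ""] <- NA_character_
  .bad_rows(duplicated(df$sample_id), path, "duplicate sample_id")
  .bad_rows(!(df$assay_type %in% c("monoculture", "mixture")), path,
            "assay_type must be monoculture or mixture")
  is_mix <- df$assay_type == "mixture"
  .bad_rows(is_mix & is.na(df$strain_j), path,
            "mixture samples need strain_j")
  .bad_rows(is_mix & !(df$initial_fraction_i > 0 & df$initial_fraction_i < 1),
            path, "mixture initial_fraction_i must lie in (0, 1)")
  .bad_rows(!is_mix & df$initial_fraction_i != 1, path,
            "monoculture initial_fraction_i must equal 1")
  .bad_rows(!(df$initial_cells_total > 0), path,
            "initial_cells_total must be positive")
  .bad_rows(!(df$resuspension_volume_ul > 0), path,
            "resuspension_volume_ul must be positive")
  df
}

#' Read a strain table
#'
#' Expected columns: `strain_id`, `display_name`, `resistance_marker`;
#' optional `role_hint`, `mutation`, `background`.
#'
#' @param path Path to `strains.csv`.
#' @return Validated data frame with the optional columns filled in.
#' @export
read_strains <- function(path) {
  df <- .read_csv_strict(path)
  .require_cols(df, c("strain_id", "display_name", "resistance_marker"), path)
  .bad_rows(duplicated(df$strain_id), path, "duplicate strain_id")
  .bad_rows(!(df$resistance_marker %in%
                c("none", "kanamycin", "oxytetracycline", "rifampicin")),
            path, "unknown resistance_marker")
  if (is.null(df$role_hint)) df$role_hint <- "unknown"
  if (is.null(df$mutation)) df$mutation <- ""
  if (is.null(df$background)) df$background <- ""
  df$mutation[is.na(df$mutation)] <- ""
  df$background[is.na(df$background)] <- ""
  df
}

#' Write a simulated dataset to a directory
#'
#' Writes `plates.csv`, `samples.csv`, `strains.csv`, `truth.csv`
#' (per-sample realized truth) and, when mixtures were simulated,
#' `truth_pairs.csv` (true `C_i(j)` / `W_ij`).
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(plates = file.path(dir, "plates.csv"),
             samples = file.path(dir, "samples.csv"),
             strains = file.path(dir, "strains.csv"),
             truth = file.path(dir, "truth.csv"))
  write.csv(dataset$plates, paths["plates"], row.names = FALSE)
  write.csv(dataset$samples, paths["samples"], row.names = FALSE)
  write.csv(dataset$strains, paths["strains"], row.names = FALSE)
  write.csv(dataset$truth$samples, paths["truth"], row.names = FALSE)
  if (!is.null(dataset$truth$pairs)) {
    paths <- c(paths, truth_pairs = file.path(dir, "truth_pairs.csv"))
    write.csv(dataset$truth$pairs, paths["truth_pairs"], row.names = FALSE)
  }
  invisible(paths)
}

#' Write a simulation config to YAML
#'
#' @param config A [simulation_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- unclass(config)
  x$strains <- lapply(seq_len(nrow(config$strains)),
                      function(r) as.list(config$strains[r, ]))
  x$interactions <- if (is.null(config$interactions)) NULL else
    lapply(seq_len(nrow(config$interactions)),
           function(r) as.list(config$interactions[r, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' Round-trips the output of [write_sim_config()].
#'
#' @param path YAML path.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  strains <- do.call(rbind, lapply(x$strains, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  interactions <- if (is.null(x$interactions)) NULL else
    do.call(rbind, lapply(x$interactions, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  simulation_config(strains, interactions,
                    replicate_noise_sd = x$replicate_noise_sd,
                    n_replicates = x$n_replicates,
                    mix_fraction = x$mix_fraction,
                    inoculum_total = x$inoculum_total,
                    dilution_exponents = x$dilution_exponents,
                    plated_volume_ul = x$plated_volume_ul,
                    resuspension_volume_ul = x$resuspension_volume_ul,
                    detection_limit = x$detection_limit,
                    exact_counts = x$exact_counts,
                    seed = x$seed)
}
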