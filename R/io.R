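#' Write a curve as CSV with a self-describing YAML header
#'
#' Writes two- or three-column (x, y\[, sigma\]) data preceded by a
#' comment-prefixed YAML block recording units, temperature, seed and any
#' ground-truth parameters, so fixture files stand alone.
#'
#' @param x,y,sigma numeric columns (`sigma` optional)
#' @param path output file path
#' @param meta named list written as the YAML header
#' @param col_names column names for the CSV body
#' @return `path`, invisibly
#' @export
write_curve_csv <- function(x, y, sigma = NULL, path,
                            meta = list(), col_names = c("x", "y", "sigma")) {
  df <- if (is.null(sigma)) data.frame(x = x, y = y)
        else data.frame(x = x, y = y, sigma = sigma)
  names(df) <- col_names[seq_len(ncol(df))]
  header <- if (length(meta) > 0) {
    paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  } else character(0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a curve CSV written by [write_curve_csv()]
#'
#' @param path file path
#' @return list with `data` (data frame) and `meta` (named list from the
#'   YAML header, empty when absent)
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "# ")
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1 else length(lines)
  meta <- if (n_hdr > 0) {
    yaml::yaml.load(paste(substring(lines[seq_len(n_hdr)], 3), collapse = "\n"))
  } else list()
  data <- utils::read.csv(text = paste(lines[-seq_len(max(n_hdr, 0))],
                                       collapse = "\n"))
  list(data = data, meta = meta)
}

#' Write an FID signal to CSV
#'
#' @param signal an `fid_signal`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fid_csv <- function(signal, path) {
  meta <- list(kind = "fid", units = list(time = "us", amplitude = "a.u."),
               temperature_C = signal$temperature, seed = signal$seed,
               model_id = signal$model_id,
               truth = unclass(signal$truth))
  write_curve_csv(signal$times, signal$amplitudes, signal$sigma, path, meta,
                  col_names = c("time_us", "amplitude", "sigma"))
}

#' Read an FID signal from CSV
#'
#' @param path file path
#' @return an `fid_signal`
#' @export
read_fid_csv <- function(path) {
  r <- read_curve_csv(path)
  truth <- if (!is.null(r$meta$truth)) do.call(relax_params, r$meta$truth) else NULL
  structure(list(times = r$data$time_us, amplitudes = r$data$amplitude,
                 sigma = r$data$sigma, temperature = r$meta$temperature_C,
                 truth = truth, model_id = r$meta$model_id,
                 seed = r$meta$seed),
            class = "fid_signal")
}

#' Serialise an FID fit result to JSON
#'
#' @param fit an `fid_fit`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path) {
  out <- list(model_id = fit$model_id, chi2_min = fit$chi2_min,
              converged = fit$converged, params = unclass(fit$params))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
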