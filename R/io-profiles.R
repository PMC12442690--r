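#' @include AllClasses.R AllGenerics.R
NULL

.profile_header <- c("experiment", "residue", "nucleus", "temperature_K",
                     "B0_MHz_1H", "field_Hz", "time_s", "observe", "x", "y",
                     "sigma")

#' Write a ProfileDataset as TSV
#'
#' One row per data point in the package's profile dialect: tab-separated,
#' UTF-8, '.' decimal separator, '#' comment lines permitted, exact header
#' \code{experiment residue nucleus temperature_K B0_MHz_1H field_Hz time_s
#' observe x y sigma}. \code{field_Hz} holds the CEST B1 (or R1rho
#' spin-lock) field and \code{time_s} the saturation time Tex or CPMG
#' constant-time Tcp. One experiment type per file. Values round-trip at 12
#' significant digits.
#'
#' @param dataset a [ProfileDataset-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeProfiles <- function(dataset, path) {
  stopifnot(is(dataset, "ProfileDataset"))
  df <- as.data.frame(dataset)
  if (length(unique(df$experiment)) > 1)
    stop("one experiment type per file: got ",
         paste(unique(df$experiment), collapse = ", "))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(.profile_header, collapse = "\t"), con)
  utils::write.table(df[.profile_header], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a profile TSV into a ProfileDataset
#'
#' Malformed rows are reported with their line numbers; a missing
#' \code{sigma} column is allowed and filled with \code{defaultSigma} (with
#' a message).
#'
#' @param path TSV file in the [writeProfiles()] dialect.
#' @param defaultSigma sigma applied when the column is absent.
#' @return a [ProfileDataset-class].
#' @export
readProfiles <- function(path, defaultSigma = 0.005) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  if (!length(lineno)) stop("no data in ", path)
  hdr <- strsplit(lines[lineno[1]], "\t", fixed = TRUE)[[1]]
  has_sigma <- "sigma" %in% hdr
  need <- setdiff(.profile_header, "sigma")
  missing_cols <- setdiff(need, hdr)
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  body <- lineno[-1]
  rows <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(hdr))
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(body[bad], collapse = ", "))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- hdr
  numcols <- c("temperature_K", "B0_MHz_1H", "field_Hz", "time_s", "x", "y",
               if (has_sigma) "sigma")
  for (cc in numcols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !(df[[cc]] %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric value in column ", cc, " at line(s): ",
           paste(body[bad], collapse = ", "))
    df[[cc]] <- v
  }
  if (!has_sigma) {
    message("sigma column absent; applying default sigma = ", defaultSigma)
    df$sigma <- defaultSigma
  }
  if (length(unique(df$experiment)) > 1)
    stop("one experiment type per file")
  key <- paste(df$residue, df$nucleus, df$temperature_K, df$B0_MHz_1H,
               df$field_Hz, df$time_s, df$observe, sep = "|")
  profs <- lapply(unique(key), function(k) {
    d <- df[key == k, , drop = FALSE]
    meta <- switch(d$experiment[1],
      cest = list(B1_Hz = d$field_Hz[1], Tex_s = d$time_s[1],
                  observe = d$observe[1]),
      cpmg = list(Tcp_s = d$time_s[1], observe = d$observe[1]),
      r1rho = list(omega1_Hz = d$field_Hz[1], observe = d$observe[1]))
    relaxationProfile(d$experiment[1], d$residue[1], d$nucleus[1],
                      d$temperature_K[1], d$B0_MHz_1H[1], meta,
                      data.frame(x = d$x, y = d$y, sigma = d$sigma))
  })
  profileDataset(profs)
}

#' Write a structured JSON fit report
#'
#' Serializes a [FitResult-class] (topology, parameter table with values and
#' standard deviations, chi-square/BIC/AIC statistics, per-profile residual
#' summaries, convergence diagnostics) plus provenance (package version,
#' optional seed) to JSON.
#'
#' @param fit a [FitResult-class].
#' @param path output file.
#' @param seed optional seed recorded in the provenance block.
#' @return invisibly, the path.
#' @export
writeFitReport <- function(fit, path, seed = NULL) {
  stopifnot(is(fit, "FitResult"))
  rep <- list(
    provenance = list(
      package = "foldex",
      version = as.character(utils::packageVersion("foldex")),
      seed = seed),
    topology = fit@topology,
    parameters = fit@parameters,
    stats = fit@stats[c("chi2", "reduced_chi2", "bic", "aic", "n_points",
                        "n_params")],
    profile_residuals = fit@stats$profiles,
    convergence = fit@convergence[c("converged", "info", "niter", "start")])
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON fit report
#'
#' @param path report written by [writeFitReport()].
#' @return named list.
#' @export
readFitReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
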