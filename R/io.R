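num17 <- function(x) sprintf("%.17g", x)

write_table_with_header <- function(path, fields, data, meta = NULL) {
  lines <- paste("#! FIELDS", paste(fields, collapse = " "))
  for (nm in names(meta)) {
    v <- meta[[nm]]
    lines <- c(lines, paste("#! SET", nm,
                            if (is.numeric(v)) num17(v) else as.character(v)))
  }
  data <- as.matrix(data)
  cols <- lapply(seq_len(ncol(data)), function(j) num17(data[, j]))
  rows <- do.call(paste, c(cols, list(sep = " ")))
  writeLines(c(lines, rows), path)
  invisible(path)
}

read_table_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#!")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(sub("^#! FIELDS ", "", hdr[grepl("^#! FIELDS", hdr)]),
                     "\\s+")[[1]]
  meta <- list()
  for (s in hdr[grepl("^#! SET", hdr)]) {
    p <- strsplit(sub("^#! SET ", "", s), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(p[-1]))
    meta[[p[1]]] <- if (any(is.na(v))) p[-1] else v
  }
  dat <- if (length(body)) {
    parts <- strsplit(trimws(body), "\\s+")
    m <- matrix(as.numeric(unlist(parts, use.names = FALSE)),
                ncol = length(fields), byrow = TRUE)
    colnames(m) <- fields
    as.data.frame(m)
  } else {
    stats::setNames(as.data.frame(matrix(numeric(0), 0, length(fields))), fields)
  }
  list(data = dat, meta = meta)
}

#' Read and write COLVAR-style collective variable series
#'
#' Whitespace-delimited text with a `#! FIELDS time cv1 cv2 ...` header
#' and optional `#! SET key value` metadata lines (umbrella windows store
#' their centre and elastic constant this way).  Values are written with
#' 17 significant digits, so a write/read cycle reproduces the parsed
#' numbers exactly.
#'
#' @param times Time values, ps.
#' @param values Matrix (or vector) of CV values, one row per time.
#' @param names CV column names.
#' @param path File path.
#' @param meta Optional named list of metadata values.
#' @return `read_colvar()` returns a list with `data` (data frame) and
#'   `meta`.
#' @export
write_colvar <- function(times, values, names, path, meta = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  write_table_with_header(path, c("time", names), cbind(times, values), meta)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) read_table_with_header(path)

#' Read and write HILLS files
#'
#' The deposited-hill record of a metadynamics run in the PLUMED dialect:
#' `#! FIELDS time center_<cv>... sigma_<cv>... height biasf` plus
#' metadata lines carrying the schedule and grid so the free energy
#' surface can be rebuilt from the file alone (use
#' [reconstruct_fes()] with `source = "hills"`).
#'
#' @param log A `hills_log` from [run_metad()].
#' @param path File path.
#' @return `read_hills()` returns a `hills_log`.
#' @export
write_hills <- function(log, path) {
  stopifnot(inherits(log, "hills_log"))
  ncv <- length(log$cv_names)
  biasf <- log$delta_T / log$temperature
  meta <- list(omega = log$schedule$omega, tau = log$schedule$tau,
               delta_T = log$delta_T, temperature = log$temperature,
               cv_names = paste(log$cv_names, collapse = ","))
  for (k in seq_len(ncv)) {
    meta[[paste0("range_", log$cv_names[k])]] <-
      paste(num17(log$cv_ranges[[k]]), collapse = ",")
    meta[[paste0("bins_", log$cv_names[k])]] <- log$bin_counts[k]
  }
  # PLUMED dialect: centre columns carry the bare CV names
  fields <- c("time", log$cv_names, paste0("sigma_", log$cv_names),
              "height", "biasf")
  write_table_with_header(
    path, fields,
    cbind(as.matrix(log$hills), biasf = rep(biasf, nrow(log$hills))), meta)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  r <- read_table_with_header(path)
  cvn <- strsplit(r$meta$cv_names, ",")[[1]]
  ncv <- length(cvn)
  hills <- r$data[, seq_len(2 + 2 * ncv)]
  names(hills) <- c("time", paste0("center_", cvn), paste0("sigma_", cvn),
                    "height")
  ranges <- lapply(cvn, function(nm)
    as.numeric(strsplit(r$meta[[paste0("range_", nm)]], ",")[[1]]))
  structure(list(
    schedule = wt_schedule(omega = r$meta$omega, tau = r$meta$tau,
                           delta_T = r$meta$delta_T,
                           sigmas = as.numeric(hills[1, 1 + ncv + seq_len(ncv)])),
    hills = hills, cv_names = cvn, cv_ranges = ranges,
    bin_counts = vapply(cvn, function(nm)
      as.integer(r$meta[[paste0("bins_", nm)]]), integer(1)),
    delta_T = r$meta$delta_T, temperature = r$meta$temperature,
    bias_final = NULL, bias_avg = NULL, n_avg = 0, n_clamped = 0),
    class = "hills_log")
}

#' Read and write free energy surface grids
#'
#' Long-format text (`cv1 [cv2] free_energy`) with the grid geometry in
#' the header; unvisited bins are written as `nan`.
#'
#' @param fes A `free_energy_surface`.
#' @param path File path.
#' @return `read_fes()` returns a `free_energy_surface`.
#' @export
write_fes <- function(fes, path) {
  ncv <- length(fes$axes)
  pts <- if (ncv == 1) matrix(fes$axes[[1]], ncol = 1) else
    as.matrix(expand.grid(fes$axes[[1]], fes$axes[[2]]))
  meta <- list(cv_names = paste(fes$cv_names, collapse = ","),
               bins = paste(vapply(fes$axes, length, integer(1)), collapse = ","))
  fe <- as.numeric(fes$free_energy)
  fe[is.na(fe)] <- NaN   # unvisited bins are written as nan
  write_table_with_header(path, c(fes$cv_names, "free_energy"),
                          cbind(pts, fe), meta)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  r <- read_table_with_header(path)
  cvn <- strsplit(r$meta$cv_names, ",")[[1]]
  bins <- as.integer(strsplit(as.character(r$meta$bins), ",")[[1]])
  fe <- r$data$free_energy
  axes <- if (length(cvn) == 1) list(unique(r$data[[cvn[1]]])) else
    list(unique(r$data[[cvn[1]]]), unique(r$data[[cvn[2]]]))
  dim(fe) <- c(bins[1], if (length(bins) > 1) bins[2] else 1L)
  structure(list(axes = axes, cv_names = cvn, free_energy = fe,
                 visited = !is.na(fe), scale = NA_real_),
            class = "free_energy_surface")
}

#' Read and write 1-D free energy profiles
#'
#' Two- or three-column text (`rc free_energy [stderr]`).
#'
#' @param profile A [profile1d()].
#' @param path File path.
#' @return `read_pmf()` returns a [profile1d()].
#' @export
write_pmf <- function(profile, path) {
  dat <- cbind(profile$rc, profile$free_energy)
  fields <- c(profile$cv_name, "free_energy")
  if (!is.null(profile$uncertainty)) {
    dat <- cbind(dat, profile$uncertainty)
    fields <- c(fields, "stderr")
  }
  write_table_with_header(path, fields, dat)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  r <- read_table_with_header(path)
  profile1d(r$data[[1]], r$data$free_energy,
            uncertainty = r$data$stderr, align = FALSE,
            cv_name = names(r$data)[1])
}

#' Read and write ABF estimator state
#'
#' Text grid (`bin_center count mean_force`) plus the binning metadata,
#' for restart and inspection.
#'
#' @param est An [abf_estimator()].
#' @param path File path.
#' @return `read_abf_state()` returns an [abf_estimator()].
#' @export
write_abf_state <- function(est, path) {
  write_table_with_header(
    path, c("bin_center", "count", "mean_force"),
    cbind(est$bin_centers, est$counts,
          ifelse(est$counts > 0, est$force_sums / est$counts, 0)),
    meta = list(lo = est$lo, hi = est$hi, n_bins = est$n_bins,
                ramp_threshold = est$ramp_threshold, cv = est$cv))
}

#' @rdname write_abf_state
#' @export
read_abf_state <- function(path) {
  r <- read_table_with_header(path)
  est <- abf_estimator(r$meta$lo, r$meta$hi,
                       (r$meta$hi - r$meta$lo) / r$meta$n_bins,
                       r$meta$ramp_threshold, cv = as.character(r$meta$cv))
  est$counts <- r$data$count
  est$force_sums <- r$data$mean_force * r$data$count
  est
}
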