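#' @title Plain-text file dialects
#' @name calokin-io
#' @description Readers and writers for the package's plain-text formats:
#'   thermogram CSV (`# calokin-thermogram v1` header, `key=value` metadata
#'   lines, then `time_s,power_ucal_per_s`), titration CSV
#'   (`# calokin-titration v1`, metadata, then `injection_ul,heat_ucal`)
#'   and rate-profile CSV (`s_uM,v_uM_per_s`). Writers emit exactly this
#'   dialect; readers accept comma- or tab-separated data lines.
NULL

.split_fields <- function(line) strsplit(line, "[,\t]")[[1]]

.read_header <- function(lines, magic) {
  if (!startsWith(trimws(lines[1]), magic))
    stop(sprintf("not a %s file (missing '%s' header)", magic, magic),
         call. = FALSE)
  meta <- list()
  i <- 2L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) { i <- i + 1L; next }
    if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
      i <- i + 1L
    } else break
  }
  list(meta = meta, data_start = i)
}

.read_two_cols <- function(lines, start, expected_header) {
  hdr <- .split_fields(trimws(lines[start]))
  if (!identical(tolower(trimws(hdr)), expected_header))
    stop(sprintf("line %d: expected column header '%s'", start,
                 paste(expected_header, collapse = ",")), call. = FALSE)
  rows <- lines[(start + 1L):length(lines)]
  rows <- rows[trimws(rows) != ""]
  vals <- lapply(seq_along(rows), function(j) {
    f <- suppressWarnings(as.numeric(.split_fields(rows[j])))
    if (length(f) != 2L || anyNA(f))
      stop(sprintf("line %d: malformed data row '%s'", start + j, rows[j]),
           call. = FALSE)
    f
  })
  m <- do.call(rbind, vals)
  list(a = m[, 1], b = m[, 2])
}

#' Write / read a thermogram CSV
#'
#' @param g a [thermogram()].
#' @param path file path.
#' @return `write_thermogram` returns `path` invisibly; `read_thermogram`
#'   returns a `thermogram`.
#' @export
write_thermogram <- function(g, path) {
  stopifnot(inherits(g, "thermogram"))
  m <- g$meta
  hdr <- c("# calokin-thermogram v1",
           sprintf("cell_volume_ul=%.10g", m$cell_volume * 1e6),
           sprintf("enzyme_uM=%.10g", m$enzyme * 1e6),
           sprintf("s0_uM=%.10g", m$S0 * 1e6),
           sprintf("cosubstrate_uM=%.10g", m$cosubstrate * 1e6),
           sprintf("p0_uM=%.10g", m$P0 * 1e6),
           sprintf("temp_C=%.10g", m$temp_K - 273.15),
           sprintf("injection_end_s=%.10g", m$injection_end_s),
           "time_s,power_ucal_per_s")
  rows <- sprintf("%.10g,%.10g", g$t, g$power)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  h <- .read_header(lines, "# calokin-thermogram v1")
  need <- c("cell_volume_ul", "s0_uM")
  miss <- setdiff(need, names(h$meta))
  if (length(miss))
    stop("missing metadata field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- function(key, default = NA_real_)
    if (!is.null(h$meta[[key]])) as.numeric(h$meta[[key]]) else default
  cols <- .read_two_cols(lines, h$data_start,
                         c("time_s", "power_ucal_per_s"))
  thermogram(t = cols$a, power = cols$b,
             cell_volume = num("cell_volume_ul") * 1e-6,
             enzyme = num("enzyme_uM") * 1e-6,
             S0 = num("s0_uM") * 1e-6,
             cosubstrate = num("cosubstrate_uM") * 1e-6,
             P0 = num("p0_uM", 0) * 1e-6,
             temp_K = num("temp_C", 30) + 273.15,
             injection_end_s = num("injection_end_s", 0),
             id = basename(path))
}

#' Write / read a rate-profile CSV
#'
#' Columns `s_uM,v_uM_per_s`; concentrations in micromolar on disk,
#' mol/L in memory.
#'
#' @param p a [rate_profile()].
#' @param path file path.
#' @export
write_rate_profile <- function(p, path) {
  stopifnot(inherits(p, "rate_profile"))
  writeLines(c("s_uM,v_uM_per_s",
               sprintf("%.10g,%.10g", p$S * 1e6, p$v * 1e6)), path)
  invisible(path)
}

#' @rdname write_rate_profile
#' @export
read_rate_profile <- function(path) {
  lines <- readLines(path)
  cols <- .read_two_cols(lines, 1L, c("s_um", "v_um_per_s"))
  rate_profile(S = cols$a * 1e-6, v = cols$b * 1e-6, source = basename(path))
}

#' Write / read a titration CSV
#'
#' @param t a [titration()].
#' @param path file path.
#' @export
write_titration <- function(t, path) {
  stopifnot(inherits(t, "titration"))
  hdr <- c("# calokin-titration v1",
           sprintf("cell_volume_ul=%.10g", t$V0 * 1e6),
           sprintf("cell_conc_uM=%.10g", t$M0 * 1e6),
           sprintf("syringe_conc_uM=%.10g", t$X_syr * 1e6),
           sprintf("temp_C=%.10g", t$T_K - 273.15),
           "injection_ul,heat_ucal")
  rows <- sprintf("%.10g,%.10g", t$inj_vol * 1e6, t$heats)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  h <- .read_header(lines, "# calokin-titration v1")
  need <- c("cell_volume_ul", "cell_conc_uM", "syringe_conc_uM")
  miss <- setdiff(need, names(h$meta))
  if (length(miss))
    stop("missing metadata field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- function(key, default = NA_real_)
    if (!is.null(h$meta[[key]])) as.numeric(h$meta[[key]]) else default
  cols <- .read_two_cols(lines, h$data_start, c("injection_ul", "heat_ucal"))
  titration(V0 = num("cell_volume_ul") * 1e-6,
            M0 = num("cell_conc_uM") * 1e-6,
            X_syr = num("syringe_conc_uM") * 1e-6,
            inj_vol = cols$a * 1e-6,
            heats = cols$b,
            temp_C = num("temp_C", 30),
            id = basename(path))
}
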