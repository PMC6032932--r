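fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ",
                                     tz = "UTC")

#' Write a microclimate table as long-format CSV
#'
#' Long format with columns `time` (ISO-8601, UTC), `height_m`,
#' `variable` (`par`, `ta`, `rh`, `wind`), `value`, plus the derived
#' columns `d_kpa` and `h_source` repeated on each row of a
#' (time, height) pair.
#'
#' @param records Wide microclimate table with columns `time`, `height`,
#'   `PAR`, `T_A`, `h`, `U`, and optionally `D`, `h_source`.
#' @param path Output file path.
#' @export
write_microclimate_csv <- function(records, path) {
  if (!"D" %in% names(records)) records <- derive_microclimate(records)
  vars <- c(par = "PAR", ta = "T_A", rh = "h", wind = "U")
  long <- do.call(rbind, lapply(names(vars), function(v) {
    data.frame(time = fmt_time(records$time), height_m = records$height,
               variable = v, value = records[[vars[[v]]]],
               d_kpa = records$D, h_source = records$h_source)
  }))
  long <- long[order(long$time, long$height_m, long$variable), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format microclimate CSV
#'
#' Inverse of [write_microclimate_csv()]: pivots the long table back to one
#' row per (time, height) with columns `PAR`, `T_A`, `h`, `U`, recomputing
#' `D` when the file does not carry it.
#'
#' @param path Input file path.
#' @param k [tetens_constants()] used when `D` must be recomputed.
#' @return Wide microclimate data frame.
#' @export
read_microclimate_csv <- function(path, k = tetens_constants()) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "height_m", "variable", "value") %in% names(long)))
  key <- paste(long$time, long$height_m)
  ukey <- !duplicated(key)
  out <- data.frame(time = parse_time(long$time[ukey]),
                    height = long$height_m[ukey])
  okey <- key[ukey]
  vars <- c(par = "PAR", ta = "T_A", rh = "h", wind = "U")
  for (v in names(vars)) {
    sub <- long[long$variable == v, ]
    out[[vars[[v]]]] <- sub$value[match(okey, paste(sub$time, sub$height_m))]
  }
  if ("h_source" %in% names(long)) {
    out$h_source <- long$h_source[match(okey, key)]
  }
  if ("d_kpa" %in% names(long)) {
    out$D <- long$d_kpa[match(okey, key)]
  } else {
    out <- derive_microclimate(out, k)
  }
  out[order(out$time, out$height), ]
}

#' Write / read a leaf-trait CSV
#'
#' Columns: `leaf_id`, `species`, `width_m`, `length_m`, `area_m2`,
#' `thickness_mm`, `lma_g_m2`, `ldmc_g_g`, `height_m`, `angle_deg` (plus
#' any extra columns, e.g. generator truths, passed through).
#'
#' @param traits Trait data frame.
#' @param path File path.
#' @export
write_traits_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits_csv
#' @export
read_traits_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a stomatal spot-measurement CSV
#'
#' Columns: `leaf_id`, `species`, `time` (ISO-8601), `d_kpa`,
#' `gs_mmol_m2_s`.
#'
#' @param spots Spot table with columns `leaf_id`, `species`, `time`, `D`,
#'   `g_s`.
#' @param path File path.
#' @export
write_spots_csv <- function(spots, path) {
  utils::write.csv(
    data.frame(leaf_id = spots$leaf_id, species = spots$species,
               time = fmt_time(spots$time), d_kpa = spots$D,
               gs_mmol_m2_s = spots$g_s),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(leaf_id = d$leaf_id, species = d$species,
             time = parse_time(d$time), D = d$d_kpa, g_s = d$gs_mmol_m2_s)
}

#' Write / read an observed leaf temperature-difference CSV
#'
#' @param series Leaf series with a `time` column; all other columns are
#'   passed through.
#' @param path File path.
#' @export
write_leaf_dt_csv <- function(series, path) {
  series$time <- fmt_time(series$time)
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_leaf_dt_csv
#' @export
read_leaf_dt_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$time <- parse_time(d$time)
  d
}
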