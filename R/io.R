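# Online-dataset container, CSV round-trip and flat key-value run configs.

.DATASET_COLS <- c("time_days", "perfusion_rate_per_day",
                   "glucose_mmol_per_L", "lactate_mmol_per_L")

#' Online sensor dataset
#'
#' The sensor-facing view of a run: aligned 10 s series of the perfusion
#' rate, (filtered) glucose and lactate, optionally normalized dissolved
#' oxygen, plus the off-line initial cell concentration `xI` (always known)
#' and final concentration `xF` (training only).
#'
#' @param time_days uniform time grid \[days\].
#' @param D perfusion rate series \[1/day\].
#' @param S glucose series \[mmol/L\].
#' @param P lactate series \[mmol/L\].
#' @param Cprime optional normalized dissolved-oxygen series \[fraction\].
#' @param xI initial cell concentration \[10^6 cells/mL\].
#' @param xF final cell concentration, `NA` when unknown.
#' @param cfg the generating/observing [run_config()].
#' @return An `online_dataset` (data frame + metadata attributes).
#' @export
online_dataset <- function(time_days, D, S, P, Cprime = NULL, xI, xF = NA_real_,
                           cfg = NULL) {
  n <- length(time_days)
  if (length(D) != n || length(S) != n || length(P) != n ||
      (!is.null(Cprime) && length(Cprime) != n))
    stop("all series must share the time grid's length", call. = FALSE)
  if (n < 2L) stop("dataset needs at least two samples", call. = FALSE)
  sp <- diff(time_days)
  if (max(sp) - min(sp) > 1e-6)
    stop("time grid is not uniform (spacing varies by more than 1e-6 days)",
         call. = FALSE)
  if (!is.finite(xI) || xI <= 0) stop("xI must be positive", call. = FALSE)
  for (nm in c("D", "S", "P")) {
    v <- get(nm)
    bad <- which(v < 0)
    if (length(bad))
      stop(sprintf("negative %s value at row %d",
                   switch(nm, D = "perfusion-rate", S = "glucose",
                          P = "lactate"), bad[1L]), call. = FALSE)
  }
  df <- data.frame(time_days = time_days, perfusion_rate_per_day = D,
                   glucose_mmol_per_L = S, lactate_mmol_per_L = P)
  if (!is.null(Cprime)) df$do_fraction <- Cprime
  structure(df, class = c("online_dataset", "data.frame"),
            xI = as.numeric(xI), xF = as.numeric(xF), run_config = cfg,
            dt = stats::median(sp))
}

#' @export
print.online_dataset <- function(x, ...) {
  cat(sprintf("Online dataset: %d samples every %.3g s over [%.3g, %.3g] days%s\n",
              nrow(x), attr(x, "dt") * 86400, min(x$time_days), max(x$time_days),
              if ("do_fraction" %in% names(x)) " (with DO)" else ""))
  cat(sprintf("  xI = %.3g e6 cells/mL; xF = %s\n", attr(x, "xI"),
              if (is.na(attr(x, "xF"))) "unknown" else
                sprintf("%.3g e6 cells/mL", attr(x, "xF"))))
  invisible(x)
}

#' Truncate an online dataset to a causal window
#'
#' Keeps only samples with `time <= t_max` and drops the final-concentration
#' label (`xF`) so downstream fits cannot peek at the endpoint.
#'
#' @param data an [online_dataset()].
#' @param t_max window end \[days\].
#' @param keep_xF keep the `xF` attribute (default `FALSE`, the real-time
#'   contract).
#' @return The truncated `online_dataset`.
#' @export
truncate_dataset <- function(data, t_max, keep_xF = FALSE) {
  if (!inherits(data, "online_dataset"))
    stop("'data' must be an online_dataset", call. = FALSE)
  keep <- data$time_days <= t_max + 1e-12
  if (!any(keep)) stop("window contains no data", call. = FALSE)
  out <- data[keep, , drop = FALSE]
  structure(out, class = c("online_dataset", "data.frame"),
            xI = attr(data, "xI"),
            xF = if (keep_xF) attr(data, "xF") else NA_real_,
            run_config = attr(data, "run_config"), dt = attr(data, "dt"))
}

.fmt_num <- function(x) sprintf("%.15g", x)

#' Write an online dataset to CSV
#'
#' Plain CSV with header `time_days, perfusion_rate_per_day,
#' glucose_mmol_per_L, lactate_mmol_per_L` (plus `do_fraction` when present),
#' preceded by `#`-prefixed metadata lines carrying `xI`, `xF` and the run
#' configuration. Numbers are written with 15 significant digits so a
#' write-read round trip is lossless to 1e-12.
#'
#' @param data an [online_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(data, path) {
  if (!inherits(data, "online_dataset"))
    stop("'data' must be an online_dataset", call. = FALSE)
  meta <- c(xI = attr(data, "xI"))
  if (!is.na(attr(data, "xF"))) meta <- c(meta, xF = attr(data, "xF"))
  cfg <- attr(data, "run_config")
  if (!is.null(cfg)) meta <- c(meta, unlist(unclass(cfg)))
  meta <- meta[!is.na(meta)]
  hdr <- sprintf("# %s = %s", names(meta), .fmt_num(meta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(data), collapse = ","), con)
  mat <- vapply(data, .fmt_num, character(nrow(data)))
  writeLines(apply(matrix(mat, nrow = nrow(data)), 1L, paste, collapse = ","),
             con)
  invisible(path)
}

#' Read an online dataset from CSV
#'
#' Inverse of [write_dataset()]: parses the `#` metadata lines, validates the
#' required columns, grid uniformity and non-negativity, and rebuilds the
#' [online_dataset()] (with its [run_config()] when the metadata carry one).
#'
#' @param path CSV file path.
#' @return An [online_dataset()].
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=")[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- as.numeric(trimws(kv[2L]))
  }
  body <- lines[!is_meta]
  if (length(body) < 3L) stop("dataset file has no data rows", call. = FALSE)
  cols <- strsplit(body[1L], ",")[[1L]]
  if (!all(.DATASET_COLS %in% cols))
    stop(sprintf("missing required column(s): %s",
                 paste(setdiff(.DATASET_COLS, cols), collapse = ", ")),
         call. = FALSE)
  parts <- strsplit(body[-1L], ",")
  nf <- lengths(parts)
  if (any(nf != length(cols)))
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 which(nf != length(cols))[1L], length(cols),
                 nf[nf != length(cols)][1L]), call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = length(cols), byrow = TRUE)
  colnames(m) <- cols
  if (is.null(meta$xI)) stop("metadata must carry xI", call. = FALSE)
  cfg_keys <- c("tI", "tsed", "tF", "Dmin", "Kp", "Ki", "Kd", "SI", "Ssp",
                "XI", "XF", "V")
  cfg <- NULL
  if (all(c("tI", "tsed", "tF", "SI", "Ssp", "XI") %in% names(meta))) {
    args <- meta[intersect(cfg_keys, names(meta))]
    cfg <- do.call(run_config, args)
  }
  online_dataset(time_days = m[, "time_days"],
                 D = m[, "perfusion_rate_per_day"],
                 S = m[, "glucose_mmol_per_L"],
                 P = m[, "lactate_mmol_per_L"],
                 Cprime = if ("do_fraction" %in% cols) m[, "do_fraction"],
                 xI = meta$xI, xF = if (is.null(meta$xF)) NA_real_ else meta$xF,
                 cfg = cfg)
}

.CONFIG_KEYS <- list(
  cfg = c("tI", "tsed", "tF", "Dmin", "Kp", "Ki", "Kd", "SI", "Ssp", "XI",
          "XF", "V"),
  gp = c("tlag_minus_tI", "mu_max", "nu"),
  mp = c("Yxs", "Ypx"),
  op = c("kLa", "Yxc_prime"),
  noise = c("glucose_sd", "lactate_sd", "bubble_rate", "bubble_depth",
            "bubble_duration", "seed"),
  settings = c("dt_seconds")
)

#' Read a flat key-value run configuration file
#'
#' Parses `key = value` lines (`#` comments and blank lines ignored) into a
#' [run_config()] plus optional growth/metabolic/oxygen/noise parameter
#' blocks and global settings. Unknown keys are rejected. `tlag` is stored in
#' the file as `tlag_minus_tI` (the lag period), matching how run summaries
#' are reported, and converted to absolute time here. `mu_max` may be
#' omitted when `XF` is present, in which case it is derived from the run
#' endpoints via [mu_max_from_endpoint()].
#'
#' @param path configuration file path.
#' @return A list with elements `cfg` ([run_config()]), and where the file
#'   provides them `gp`, `mp`, `op`, `noise`, `dt` \[days\].
#' @seealso [example_run_config()]
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=")
  if (any(lengths(kv) != 2L))
    stop("malformed config line (expected 'key = value')", call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  known <- unlist(.CONFIG_KEYS, use.names = FALSE)
  if (any(!keys %in% known))
    stop(sprintf("unknown config key(s): %s",
                 paste(setdiff(keys, known), collapse = ", ")), call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated config key", call. = FALSE)
  val <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  cfg_args <- Filter(Negate(is.null),
                     stats::setNames(lapply(.CONFIG_KEYS$cfg, val),
                                     .CONFIG_KEYS$cfg))
  cfg <- do.call(run_config, cfg_args)
  out <- list(cfg = cfg)
  if (!is.null(val("nu"))) {
    tlag <- cfg$tI + (val("tlag_minus_tI") %||% 0)
    mu <- val("mu_max")
    if (is.null(mu)) {
      if (is.na(cfg$XF))
        stop("config needs mu_max or XF to define the growth law",
             call. = FALSE)
      mu <- mu_max_from_endpoint(cfg$XI, cfg$XF, tlag, val("nu"), cfg$tF)
    }
    out$gp <- growth_params(tlag, mu, val("nu"))
  }
  if (!is.null(val("Yxs")))
    out$mp <- metabolic_params(val("Yxs"), val("Ypx"))
  if (!is.null(val("kLa")))
    out$op <- oxygen_params(val("kLa"), val("Yxc_prime"))
  if (!is.null(val("glucose_sd")))
    out$noise <- noise_config(glucose_sd = val("glucose_sd"),
                              lactate_sd = val("lactate_sd") %||% 0.2,
                              bubble_rate = val("bubble_rate") %||% 5,
                              bubble_depth = val("bubble_depth") %||% 2,
                              bubble_duration = val("bubble_duration") %||% 60,
                              seed = val("seed") %||% 1L)
  if (!is.null(val("dt_seconds"))) out$dt <- val("dt_seconds") / 86400
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged example run configurations
#'
#' Returns the parsed configuration of one of the six packaged example runs
#' (`"run1"` ... `"run6"`), transcribing the observed inputs and, for the
#' five training runs, the best-fit kinetic parameters of the corresponding
#' published bioreactor runs. `run3` carries no kinetic block (it is the
#' held-out test run).
#'
#' @param name one of `"run1"` ... `"run6"`.
#' @return See [read_run_config()].
#' @examples
#' rc <- example_run_config("run1")
#' rc$cfg
#' rc$gp
#' @export
example_run_config <- function(name = c("run1", "run2", "run3", "run4",
                                        "run5", "run6")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".cfg"), package = "bioshadow",
                      mustWork = TRUE)
  read_run_config(path)
}
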