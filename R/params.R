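# Parameter set for the SADC-WC system: printed point values for the
# data-supported rates, declared ranges for the estimated ones.

#' Declared bounds for the estimated parameters
#'
#' The initiation and self-conviction rates (`di`, `ci`, `se`) and the
#' excess death rates in the abuser, rehabilitation and correctional stocks
#' (`dd`, `rd`, `sd`) are not directly supported by data; they carry
#' declared ranges instead of point values. Calibration may move them only
#' within these bounds.
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
parameter_bounds <- function() {
  list(di = c(0.05, 0.10), ci = c(0.05, 0.10), se = c(0.05, 0.10),
       dd = c(0.015, 0.020), rd = c(0.015, 0.020), sd = c(0.015, 0.020))
}

#' SADC-WC parameter set
#'
#' Constructs the full rate-constant set of the model. Defaults are the
#' published point values where available; parameters published only as
#' ranges (see [parameter_bounds()]) default to their range midpoints and
#' are the natural targets for [calibrate()].
#'
#' @param b birth rate (per person-year).
#' @param d death rate in the community stock (per person-year).
#' @param r relapse rate out of rehabilitation (per year).
#' @param cc correctional-referral rate to rehabilitation (per year).
#' @param s successful-conviction fraction of cases reaching court.
#' @param c fraction of open cases reaching court per year.
#' @param fc fraction of open cases failing (not reaching court) per year.
#' @param sr successful-rehabilitation rate (per year).
#' @param m net in-migration into the community (persons per year).
#' @param sc successful-corrections (sentence-completion) rate per year;
#'   see [successful_corrections_rate()] for its derivation from the
#'   sentence-duration mix.
#' @param di,ci drug- and crime-initiation rates (per year), bounded.
#' @param se self-conviction rate (per year), bounded.
#' @param dd,rd,sd excess death rates in the D, R and S stocks (per year),
#'   bounded.
#' @param initiation_form `"frequency"` (default): initiation is
#'   `(di + ci) * C * D / N` with `N = C + D + S + R`, the standard
#'   frequency-dependent interaction term of drug-epidemic models;
#'   `"bilinear"`: the raw product `(di + ci) * C * D`, retained for
#'   fidelity experiments only (at realistic stock sizes it produces
#'   absurd magnitudes, ~1e11 persons/year).
#' @param referral_base `"R"` (default): the correctional-referral flow
#'   S -> R has magnitude `cc * R`, the published converter equation, under
#'   which referrals stay small relative to uptake; `"S"`: magnitude
#'   `cc * S`, the source-stock convention.
#' @param enforce_bounds check the bounded parameters against
#'   [parameter_bounds()] (default `TRUE`). Disable for stress tests that
#'   draw arbitrary non-negative rates.
#'
#' @return An object of class `sadcwc_params` (a named list).
#' @examples
#' p <- sadcwc_params()
#' p$sc
#' sadcwc_params(di = 0.1, ci = 0.1, se = 0.05)
#' @export
sadcwc_params <- function(b = 0.023, d = 0.013, r = 0.257, cc = 0.057,
                          s = 0.25, c = 0.25, fc = 0.75, sr = 0.7,
                          m = 152230, sc = 0.179,
                          di = 0.075, ci = 0.075, se = 0.075,
                          dd = 0.0175, rd = 0.0175, sd = 0.0175,
                          initiation_form = c("frequency", "bilinear"),
                          referral_base = c("R", "S"),
                          enforce_bounds = TRUE) {
  initiation_form <- match.arg(initiation_form)
  referral_base <- match.arg(referral_base)
  p <- list(b = b, d = d, r = r, cc = cc, s = s, c = c, fc = fc, sr = sr,
            m = m, sc = sc, di = di, ci = ci, se = se,
            dd = dd, rd = rd, sd = sd)
  num <- unlist(p)
  if (any(!is.finite(num))) stop("all parameters must be finite numbers")
  if (any(num < 0)) stop("all parameters must be non-negative")
  for (f in c("s", "c", "fc", "sr")) {
    if (p[[f]] > 1) stop(sprintf("'%s' is a fraction and must lie in [0, 1]", f))
  }
  if (enforce_bounds) {
    bd <- parameter_bounds()
    for (nm in names(bd)) {
      if (p[[nm]] < bd[[nm]][1] - 1e-12 || p[[nm]] > bd[[nm]][2] + 1e-12) {
        stop(sprintf("'%s' = %g outside its declared range [%g, %g]",
                     nm, p[[nm]], bd[[nm]][1], bd[[nm]][2]))
      }
    }
  }
  p$initiation_form <- initiation_form
  p$referral_base <- referral_base
  class(p) <- "sadcwc_params"
  p
}

#' @export
print.sadcwc_params <- function(x, ...) {
  cat("<sadcwc_params>\n")
  num <- unlist(x[!names(x) %in% c("initiation_form", "referral_base")])
  print(num)
  cat(sprintf("initiation_form: %s, referral_base: %s\n",
              x$initiation_form, x$referral_base))
  invisible(x)
}

#' Modify a parameter set
#'
#' @param params a [sadcwc_params()] object.
#' @param ... named replacements, e.g. `update_params(p, r = 0.127)`.
#' @param enforce_bounds passed through to [sadcwc_params()].
#' @return A new `sadcwc_params` object.
#' @export
update_params <- function(params, ..., enforce_bounds = TRUE) {
  stopifnot(inherits(params, "sadcwc_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  args <- unclass(params)
  args[names(repl)] <- repl
  args$enforce_bounds <- enforce_bounds
  do.call(sadcwc_params, args)
}

#' Read a parameter set from a YAML or JSON config file
#'
#' The file holds a flat mapping whose keys are the parameter symbols
#' (`b`, `d`, `r`, `cc`, `s`, `c`, `fc`, `sr`, `m`, `sc`, `di`, `ci`, `se`,
#' `dd`, `rd`, `sd`), plus optionally `initiation_form` and
#' `referral_base`. Missing keys take their defaults.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param enforce_bounds passed to [sadcwc_params()].
#' @return A `sadcwc_params` object.
#' @export
read_params <- function(path, enforce_bounds = TRUE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(vals)) stop("parameter file must contain a flat mapping")
  known <- names(formals(sadcwc_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown key(s) in parameter file: ",
                        paste(bad, collapse = ", "))
  vals$enforce_bounds <- enforce_bounds
  do.call(sadcwc_params, vals)
}

#' Write a parameter set to YAML
#'
#' @param params a `sadcwc_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sadcwc_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
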