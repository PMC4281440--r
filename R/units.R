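#' Parse a physical quantity with an optional unit suffix
#'
#' Configuration files may state quantities either as plain numbers (taken
#' to be SI: m, m/s, s, K) or as strings with an explicit unit suffix such
#' as `"5 mm/s"`, `"3 mm"`, `"36 C"`.  Everything is converted to SI units
#' and Kelvin on load; all internal computation is in SI.
#'
#' @param x numeric scalar (assumed SI) or a string `"<value> <unit>"`.
#' @param kind one of `"length"`, `"velocity"`, `"time"`, `"temperature"`,
#'   `"dimensionless"`.
#' @param field field name used in error messages.
#' @return numeric scalar in SI units (lengths in m, velocities in m/s,
#'   times in s, temperatures in K).
#' @examples
#' parse_quantity("5 mm/s", "velocity")   # 0.005
#' parse_quantity("36 C", "temperature")  # 309.15
#' @export
parse_quantity <- function(x, kind = c("length", "velocity", "time",
                                       "temperature", "dimensionless"),
                           field = deparse(substitute(x))) {
  kind <- match.arg(kind)
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop("field '", field, "': expected a single finite number")
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("field '", field, "': expected a number or a '<value> <unit>' string")
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+]?[0-9.]+(?:[eE][-+]?[0-9]+)?)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L)
    stop("field '", field, "': cannot parse quantity '", x, "'")
  val <- as.numeric(m[2])
  unit <- gsub("°", "", m[3])  # allow a degree sign before C
  if (is.na(val))
    stop("field '", field, "': cannot parse numeric part of '", x, "'")
  if (unit == "") return(val)
  conv <- switch(kind,
    length = c(m = 1, mm = 1e-3, cm = 1e-2, um = 1e-6),
    velocity = c(`m/s` = 1, `mm/s` = 1e-3, `cm/s` = 1e-2),
    time = c(s = 1, ms = 1e-3, min = 60),
    temperature = NULL,
    dimensionless = NULL
  )
  if (kind == "temperature") {
    if (unit %in% c("K")) return(val)
    if (unit %in% c("C", "degC")) return(val + 273.15)
    stop("field '", field, "': unknown temperature unit '", unit, "'")
  }
  if (kind == "dimensionless")
    stop("field '", field, "': unexpected unit '", unit, "' on dimensionless value")
  if (!unit %in% names(conv))
    stop("field '", field, "': unknown ", kind, " unit '", unit, "'")
  val * conv[[unit]]
}

# Format a number so that it round-trips through text exactly.
format_si <- function(x) format(x, digits = 17, scientific = NA, trim = TRUE)
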