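# Classed conditions used across the pipeline. Each constructor stops with a
# condition inheriting c("pcquant_<class>", "pcquant_error", "error").

pcq_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("pcquant_", class), "pcquant_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

format_error <- function(msg, ...) pcq_stop("format_error", msg, ...)
axis_ambiguity_error <- function(msg, ...) pcq_stop("axis_ambiguity_error", msg, ...)
calibration_error <- function(msg, ...) pcq_stop("calibration_error", msg, ...)
schema_error <- function(msg, ...) pcq_stop("schema_error", msg, ...)
packing_error <- function(msg, ...) pcq_stop("packing_error", msg, ...)
degenerate_histogram_error <- function(msg, ...) pcq_stop("degenerate_histogram_error", msg, ...)
frame_mismatch_error <- function(msg, ...) pcq_stop("frame_mismatch_error", msg, ...)
degenerate_baseline_error <- function(msg, ...) pcq_stop("degenerate_baseline_error", msg, ...)
degenerate_section_error <- function(msg, ...) pcq_stop("degenerate_section_error", msg, ...)
validation_error <- function(msg, ...) pcq_stop("validation_error", msg, ...)

# Scalar validators used by parameter constructors.
check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error("'%s' must be a single finite number", name)
  if (integer && x != round(x))
    validation_error("'%s' must be an integer", name)
  if (x < min || x > max || (strict_min && x <= min))
    validation_error("'%s' = %g is outside its permitted range", name, x)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    validation_error("'%s' must be TRUE or FALSE", name)
  invisible(x)
}
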