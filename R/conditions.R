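# Structured conditions so callers can catch specific failure modes
# (tryCatch(degenerate_geometry_error = ...)).

ceph_stop <- function(class, message, call = sys.call(-1), data = list()) {
  cond <- structure(
    class = c(class, "cephaloplane_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cond)
}

ceph_warn <- function(class, message, data = list()) {
  cond <- structure(
    class = c(class, "cephaloplane_warning", "warning", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  warning(cond)
}

stop_degenerate <- function(message, ...) {
  ceph_stop("degenerate_geometry_error", message, ...)
}

stop_missing_landmark <- function(missing) {
  ceph_stop("missing_landmark_error",
            sprintf("missing landmark(s): %s", paste(missing, collapse = ", ")),
            data = list(landmarks = missing))
}

stop_parse <- function(message, row = NA_integer_) {
  if (!is.na(row)) message <- sprintf("%s (row %d)", message, row)
  ceph_stop("parse_error", message, data = list(row = row))
}

stop_pairing <- function(message) ceph_stop("pairing_error", message)

stop_usage <- function(message) ceph_stop("usage_error", message)

stop_topology <- function(message) ceph_stop("topology_error", message)

stop_undefined_ratio <- function(message) ceph_stop("undefined_ratio_error", message)
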