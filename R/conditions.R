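# Classed conditions so callers (and tests) can distinguish failure modes.

mp_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "muellerpol_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

mp_check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    mp_stop("mp_invalid_argument", sprintf("`%s` must be finite numeric", name))
  }
  invisible(x)
}
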