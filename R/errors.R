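# Typed condition helpers: every validation failure raises a classed error so
# callers (and tests) can distinguish schema problems from plumbing problems.

fdg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fdgradient_error"), call = call))
}

fdg_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) fdg_stop(msg, class, call = sys.call(-1))
  invisible(TRUE)
}
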