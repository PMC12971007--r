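# Classed conditions so callers can distinguish configuration, input,
# fitting, range and domain failures programmatically.

hs_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "hemosurf_error"), call = call))
}

hs_config_error <- function(msg) hs_error(msg, "hemosurf_config_error")
hs_input_error  <- function(msg) hs_error(msg, "hemosurf_input_error")
hs_fit_error    <- function(msg) hs_error(msg, "hemosurf_fit_error")
hs_range_error  <- function(msg) hs_error(msg, "hemosurf_range_error")
hs_domain_error <- function(msg) hs_error(msg, "hemosurf_domain_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic per-component child seed from one master seed, so adding a
# generated component never perturbs the draws of the others.
child_seed <- function(seed, component) {
  stopifnot(is_scalar_number(seed))
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  (as.integer(seed) %% 1000000L) * 2011L + (h %% 2011L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# summary.lm warns on zero-residual (interpolating) fits; exact synthetic
# inputs are legitimate here, so that one advisory is muffled.
quiet_perfect <- function(expr) withCallingHandlers(expr,
  warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
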