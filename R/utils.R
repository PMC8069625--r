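# Internal helpers: classed conditions and seed management.

wd_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "wearday_error", "error")))
}

wd_config_error <- function(msg) wd_stop(msg, "wearday_config_error")
wd_schema_error <- function(msg) wd_stop(msg, "wearday_schema_error")
wd_integrity_error <- function(msg) wd_stop(msg, "wearday_integrity_error")
wd_contract_error <- function(msg) wd_stop(msg, "wearday_contract_error")
wd_convergence_error <- function(msg) wd_stop(msg, "wearday_convergence_error")
wd_domain_error <- function(msg) wd_stop(msg, "wearday_domain_error")

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a master seed; stays within the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + as.double(k) * 16807) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
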