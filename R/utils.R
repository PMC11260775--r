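# shared internal helpers

Z95 <- function() qnorm(0.975)

stop_config <- function(msg) abort(msg, class = "mrkit_config_error")
stop_data <- function(msg) abort(msg, class = "mrkit_data_error")

# collapse a character vector for messages, truncating long lists
fmt_ids <- function(x, max = 8L) {
  if (length(x) > max) {
    paste0(paste(head(x, max), collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) >= 1L && all(is.finite(x)) &&
    all(if (open_lower) x > lower else x >= lower) &&
    all(if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop_config(sprintf(
      "`%s` must be a finite number in %s%s, %s%s",
      name, if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# columns required of a harmonized instrument table
check_harmonized <- function(dat, min_snp = 1L, caller = "this method") {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(need, names(dat))
  if (length(missing) > 0) {
    stop_config(paste0("harmonized table lacks column(s): ", fmt_ids(missing)))
  }
  if (nrow(dat) < min_snp) {
    stop_data(sprintf("%s requires at least %d SNP(s), got %d",
                      caller, min_snp, nrow(dat)))
  }
  if (any(dat$se_exposure <= 0) || any(dat$se_outcome <= 0)) {
    stop_data("standard errors must be strictly positive")
  }
  invisible(dat)
}

# deterministic tie-safe ordering helper
order_by <- function(...) order(..., method = "radix")
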