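# Synthetic observed-style PK datasets generated from the model itself,
# noiseless or with multiplicative log-normal noise, so the fitting and
# validation pathways are testable without external data.

#' Noise model for synthetic PK datasets
#'
#' Log-normal noise is applied multiplicatively with the median preserved:
#' `value * exp(eps)` with `eps ~ N(0, sqrt(log(1 + cv^2)))`.
#'
#' @param kind `"none"` or `"lognormal"`.
#' @param cv coefficient of variation as a fraction (default 0.15, typical
#'   preclinical PK assay variability).
#' @param seed RNG seed used when sampling noise.
#' @param lloq lower limit of quantification (nM); values below are flagged
#'   (`below_lloq = TRUE`), not silently removed.
#' @return an object of class `mpbpk_noise`.
#' @export
noise_model <- function(kind = c("none", "lognormal"), cv = 0.15, seed = 1L,
                        lloq = NULL) {
  kind <- match.arg(kind)
  if (cv < 0) stop("'cv' must be non-negative", call. = FALSE)
  structure(list(kind = kind, cv = cv, seed = as.integer(seed), lloq = lloq),
            class = "mpbpk_noise")
}

#' Generate an observed-style PK dataset from the model
#'
#' Simulates the model, samples the lumped observables at the stated times,
#' applies the noise model and flags values below the LLOQ.  The generator
#' parameters and seed are recorded as attributes (`generator`).
#'
#' @param params an `mpbpk_params`.
#' @param schedule a [dose_schedule()] or single bolus amount (nmol).
#' @param times_h sampling times (h).
#' @param noise a [noise_model()].
#' @param observables which observables to sample.
#' @param ... passed to [simulate_pk()].
#' @return data frame `time_h, observable, value, unit, below_lloq` of
#'   class `mpbpk_dataset`.
#' @export
generate_pk_dataset <- function(params, schedule, times_h,
                                noise = noise_model("none"),
                                observables = c("plasma", "tight_total",
                                                "leaky_total"), ...) {
  prof <- simulate_pk(params, schedule, times = times_h, ...)
  idx <- match(times_h, prof$time_h)
  if (anyNA(idx)) stop("sampling times outside simulated range", call. = FALSE)
  out <- do.call(rbind, lapply(observables, function(nm) {
    if (!nm %in% names(prof$observables)) stop("unknown observable: ", nm, call. = FALSE)
    data.frame(time_h = times_h, observable = nm,
               value = prof$observables[[nm]][idx], unit = "nM")
  }))
  if (noise$kind == "lognormal" && noise$cv > 0) {
    sdlog <- sqrt(log(1 + noise$cv^2))
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(noise$seed)
    out$value <- out$value * exp(rnorm(nrow(out), 0, sdlog))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  out$below_lloq <- if (!is.null(noise$lloq)) out$value < noise$lloq else FALSE
  rownames(out) <- NULL
  attr(out, "generator") <- list(noise = noise, times_h = times_h,
                                 schedule = schedule)
  class(out) <- c("mpbpk_dataset", "data.frame")
  out
}

#' Read/write observed PK datasets
#'
#' CSV schema `time_h,observable,value,unit` with observable in
#' `plasma`, `tight_total`, `leaky_total`.
#'
#' @param dataset a dataset data frame.
#' @param path file path.
#' @export
write_pk_dataset <- function(dataset, path) {
  write.csv(dataset[, c("time_h", "observable", "value", "unit")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(path) {
  out <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_h", "observable", "value")
  if (!all(need %in% names(out)))
    stop("dataset needs columns ", paste(need, collapse = ", "), call. = FALSE)
  out
}
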