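#' Construct a tracer dataset
#'
#' A tracer dataset holds whole-body-scaled organ observations: for each
#' (organ, time) pair a mean and standard deviation of the tracer content
#' in % of the injected dose, plus the number of animals. At most one row
#' per (organ, time) is allowed.
#'
#' @param df data.frame with columns `organ`, `time`, `mean`, `sd`, `n`.
#' @param diet Diet label ("deficient", "adequate", "loaded" or other).
#' @param normalized Has the dataset been rescaled to the decaying
#'   whole-body total (see [normalize_to_decaying_total()])?
#' @return data.frame of class `fk_dataset` with attributes `diet` and
#'   `normalized`.
#' @export
tracer_dataset <- function(df, diet = "adequate", normalized = FALSE) {
  need <- c("organ", "time", "mean", "sd", "n")
  if (!all(need %in% names(df))) {
    stop("dataset needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  if (any(df$sd < 0, na.rm = TRUE)) stop("sd must be >= 0")
  if (any(df$time < 0)) stop("time must be >= 0")
  if (any(df$n < 1)) stop("n must be >= 1")
  if (anyDuplicated(df[c("organ", "time")]) > 0) {
    stop("at most one observation per (organ, time)")
  }
  df <- df[order(df$time, match(df$organ, compartment_names())), ]
  rownames(df) <- NULL
  structure(df, diet = diet, normalized = normalized,
            class = c("fk_dataset", "data.frame"))
}

#' Scale an organ iron concentration to the whole organ
#'
#' Converts a measured concentration f (e.g. tracer % dose per g, or ug
#' iron per g wet organ) with SD h into a whole-organ amount by
#' multiplying with the organ weight w (SD s). The SD of the product of
#' two independent random variables is propagated exactly:
#' sd = sqrt(f^2 s^2 + w^2 h^2 + h^2 s^2).
#'
#' @param f,h Concentration mean and SD (h >= 0).
#' @param w,s Organ weight mean and SD (w > 0, s >= 0).
#' @return List with `mean` and `sd` of the whole-organ amount.
#' @examples
#' scale_to_body(10, 1, 2, 0.2)  # mean 20, sd sqrt(8.04)
#' @export
scale_to_body <- function(f, h, w, s) {
  if (any(c(f, h, w, s) < 0)) stop("inputs must be non-negative")
  list(mean = f * w, sd = sqrt(f^2 * s^2 + w^2 * h^2 + h^2 * s^2))
}

#' Combine intestinal segment observations into one intestine compartment
#'
#' The intestinal subsections (e.g. ileum/caecum/colon) lack reliable
#' individual organ weights, so their tracer concentrations are replaced
#' by a single unweighted mean ascribed to the intestine as a whole. The
#' SD of this derived mean is propagated with the same independence rule
#' as [scale_to_body()] applied to the averaged quantity: averaging K
#' independent segments divides the combined variance by K^2, i.e.
#' sd = sqrt(sum(sd_i^2)) / K.
#'
#' @param segments data.frame with columns `organ`, `time`, `mean`, `sd`,
#'   `n`; all rows must share one timepoint.
#' @return One-row data.frame for organ `"intestine"`.
#' @export
combine_intestinal_segments <- function(segments) {
  if (nrow(segments) < 1) stop("need at least one segment")
  if (length(unique(segments$time)) != 1) {
    stop("all segments must share one timepoint")
  }
  k <- nrow(segments)
  data.frame(
    organ = "intestine",
    time = segments$time[1],
    mean = mean(segments$mean),
    sd = sqrt(sum(segments$sd^2)) / k,
    n = max(segments$n))
}

#' Rescale organ observations to the decaying whole-body total
#'
#' Injected tracer doses vary slightly from animal to animal, so the raw
#' organ sums drift around the nominal 100%. Each timepoint is rescaled by
#' a common factor so that the whole-body total follows the slow
#' physiological loss of iron: total(t) = 100 * exp(-lambda * t), with
#' lambda = 0.005/day by default (about 13% of the dose lost over a
#' 28-day experiment; whole-body residence time 1/lambda = 200 days).
#' Radioactive-decay correction is assumed to have been applied upstream.
#'
#' @param dataset An `fk_dataset` covering all 16 body compartments at
#'   every timepoint.
#' @param lambda_loss Whole-body fractional loss rate (1/day).
#' @return The normalized `fk_dataset` (means and SDs rescaled,
#'   `normalized` attribute set).
#' @export
normalize_to_decaying_total <- function(dataset, lambda_loss = 0.005) {
  stopifnot(inherits(dataset, "fk_dataset"))
  comp <- compartment_names()
  out <- dataset
  for (t in unique(dataset$time)) {
    idx <- dataset$time == t
    if (!all(comp %in% dataset$organ[idx])) {
      stop("timepoint ", t, " does not cover all body compartments")
    }
    tot <- sum(dataset$mean[idx])
    if (tot <= 0) stop("timepoint ", t, " has zero total tracer")
    fac <- 100 * exp(-lambda_loss * t) / tot
    out$mean[idx] <- dataset$mean[idx] * fac
    out$sd[idx] <- dataset$sd[idx] * fac
  }
  attr(out, "normalized") <- TRUE
  attr(out, "lambda_loss") <- lambda_loss
  out
}

#' Clip negative organ means to zero
#'
#' Residual-blood correction can overshoot for organs with a large
#' trapped blood pool (the iron-deficient spleen in particular), leaving
#' small negative tracer contents. These are physically impossible and
#' are set to zero; SDs are left untouched and the affected cells are
#' recorded in the `clipped` attribute.
#'
#' @param dataset An `fk_dataset`.
#' @return The dataset with negative means set to 0 and attribute
#'   `clipped` (data.frame `organ`, `time`, `original`).
#' @export
clip_negative <- function(dataset) {
  stopifnot(inherits(dataset, "fk_dataset"))
  neg <- dataset$mean < 0
  clipped <- data.frame(organ = dataset$organ[neg],
                        time = dataset$time[neg],
                        original = dataset$mean[neg])
  dataset$mean[neg] <- 0
  attr(dataset, "clipped") <- clipped
  dataset
}

#' Read / write tracer datasets as long-format CSV
#'
#' The on-disk format has columns
#' `diet,organ,time_days,mean_pct_dose,sd_pct_dose,n`; organ names must
#' match [compartment_names()].
#'
#' @param path CSV file path.
#' @param normalized Flag recorded on the returned dataset.
#' @return [read_tracer_csv()] returns an `fk_dataset`;
#'   [write_tracer_csv()] returns the path invisibly.
#' @export
read_tracer_csv <- function(path, normalized = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("diet", "organ", "time_days", "mean_pct_dose",
            "sd_pct_dose", "n")
  if (!all(need %in% names(raw))) {
    stop("CSV needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(raw$organ), compartment_names())
  if (length(bad) > 0) stop("unknown organs: ", paste(bad, collapse = ", "))
  tracer_dataset(
    data.frame(organ = raw$organ, time = raw$time_days,
               mean = raw$mean_pct_dose, sd = raw$sd_pct_dose, n = raw$n),
    diet = raw$diet[1], normalized = normalized)
}

#' @rdname read_tracer_csv
#' @param dataset An `fk_dataset`.
#' @export
write_tracer_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "fk_dataset"))
  out <- data.frame(diet = attr(dataset, "diet"),
                    organ = dataset$organ,
                    time_days = dataset$time,
                    mean_pct_dose = dataset$mean,
                    sd_pct_dose = dataset$sd,
                    n = dataset$n)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
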