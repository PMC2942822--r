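#' Plasma/EVF iron pool descriptors per diet
#'
#' The transferrin-bound iron pool of plasma plus extravascular fluid
#' (C_plasma/ECF, ug per 25-g mouse) converts fractional clearances into
#' absolute fluxes. The bundled defaults are back-solved from the
#' published absolute marrow influxes (15; 19; 14 ug/day for deficient,
#' adequate and loaded diet) and the corresponding plasma-to-marrow
#' clearance constants; they are derived stand-ins for the supplementary
#' plasma-iron measurements and can be overridden.
#'
#' @param diet One of `"deficient"`, `"adequate"`, `"loaded"`.
#' @param iron_content Optional override of the pool size (ug).
#' @param total_clearance Total plasma clearance (1/day), default 20.
#' @return List of class `fk_plasma_pool` with `iron_content` and
#'   `total_clearance`.
#' @export
plasma_pool <- function(diet = c("deficient", "adequate", "loaded"),
                        iron_content = NULL, total_clearance = 20) {
  diet <- match.arg(diet)
  defaults <- c(deficient = 1.13, adequate = 1.50, loaded = 2.02)
  ic <- if (is.null(iron_content)) unname(defaults[diet]) else iron_content
  if (ic <= 0 || total_clearance <= 0) {
    stop("pool size and clearance must be positive")
  }
  structure(list(diet = diet, iron_content = ic,
                 total_clearance = total_clearance),
            class = "fk_plasma_pool")
}

#' Mean residence time of iron per compartment
#'
#' The expected time an iron atom spends in compartment i once it arrives
#' there is the reciprocal of the compartment's total fractional exit
#' rate, Theta_i = 1 / (sum_j k_ji + k_oi), counting both reflux and
#' body-loss exits. A compartment with no exit has infinite residence
#' time and is flagged.
#'
#' @inheritParams rate_matrix
#' @return Named numeric vector of residence times (days), with attribute
#'   `no_exit` naming compartments without any exit.
#' @examples
#' residence_times(diet_parameters("adequate")$best_fit)
#' @export
residence_times <- function(rates, topology = build_topology()) {
  rates <- validate_rates(rates, topology)
  comp <- topology$compartments
  exit <- stats::setNames(numeric(length(comp)), comp)
  for (e in seq_len(nrow(topology$edges))) {
    src <- topology$edges$source[e]
    exit[src] <- exit[src] + rates[[topology$edges$param[e]]]
  }
  theta <- 1 / exit
  attr(theta, "no_exit") <- comp[exit == 0]
  theta
}

#' Fractional distribution of plasma iron turnover into the periphery
#'
#' Shares of the total plasma clearance carried by each of the 13
#' plasma-to-organ edges: share_i = kp_i / sum_j kp_j. The shares sum to
#' one.
#'
#' @inheritParams rate_matrix
#' @return Named numeric vector of shares (fractions), named by target
#'   organ.
#' @examples
#' plasma_shares(diet_parameters("adequate")$best_fit)["bone_marrow"]
#' @export
plasma_shares <- function(rates, topology = build_topology()) {
  rates <- validate_rates(rates, topology)
  idx <- topology$edges$source == topology$central &
    topology$edges$target != EXTERNAL
  k <- rates[topology$edges$param[idx]]
  tot <- sum(k)
  if (tot <= 0) stop("total plasma clearance must be > 0")
  stats::setNames(k / tot, topology$edges$target[idx])
}

#' Absolute steady-state iron fluxes out of plasma
#'
#' Converts fractional clearances into absolute fluxes (ug iron per 25-g
#' mouse per day): v_i = kp_i * C_plasma/ECF for every plasma-to-organ
#' edge. The bone-marrow outflux is split in proportion
#' kbon_rbc : kbon_spl between the erythrocyte and the splenic route
#' (steady state), giving the erythron-chain fluxes.
#'
#' @inheritParams rate_matrix
#' @param pool An `fk_plasma_pool`, see [plasma_pool()].
#' @return List with `plasma_influx` (named by organ, ug/day) and
#'   `erythron` (fluxes `marrow_to_rbc`, `marrow_to_spleen`,
#'   `rbc_to_spleen`, ug/day).
#' @export
absolute_fluxes <- function(rates, pool, topology = build_topology()) {
  rates <- validate_rates(rates, topology)
  C <- pool$iron_content
  shares_k <- plasma_shares(rates, topology) *
    total_plasma_clearance(rates, topology)
  v <- shares_k * C
  v_bon <- v[["bone_marrow"]]
  ktot <- rates[["kbon_rbc"]] + rates[["kbon_spl"]]
  split_rbc <- if (ktot > 0) rates[["kbon_rbc"]] / ktot else NA_real_
  erythron <- c(marrow_to_rbc = v_bon * split_rbc,
                marrow_to_spleen = v_bon * (1 - split_rbc),
                rbc_to_spleen = v_bon * split_rbc)
  list(plasma_influx = v, erythron = erythron)
}

#' Tracer-accessible iron pool sizes
#'
#' At steady state, influx and outflux of a peripheral compartment
#' balance, so its tracer-accessible iron content is
#' C_i = influx_i / (total exit rate of i). For the mammillary organs the
#' influx is the plasma edge flux kp_i * C_plasma/ECF; the erythron chain
#' (bone marrow, RBC, spleen) uses its chain influx. The duodenum is
#' excluded: its unmeasured influx of cold dietary iron breaks the tracer
#' balance, so its pool is not computable.
#'
#' @inheritParams absolute_fluxes
#' @param compartments Compartments to report; default all eligible ones.
#' @return Named numeric vector of pool sizes (ug iron per 25-g mouse).
#' @export
accessible_pool_sizes <- function(rates, pool,
                                  topology = build_topology(),
                                  compartments = NULL) {
  rates <- validate_rates(rates, topology)
  if (!is.null(compartments) && "duodenum" %in% compartments) {
    stop("pool size not computable for duodenum: ",
         "cold dietary influx violates the tracer balance")
  }
  fl <- absolute_fluxes(rates, pool, topology)
  theta <- residence_times(rates, topology)
  influx <- fl$plasma_influx
  influx[["bone_marrow"]] <- fl$plasma_influx[["bone_marrow"]]
  influx[["rbc"]] <- fl$erythron[["marrow_to_rbc"]]
  influx[["spleen"]] <- fl$erythron[["marrow_to_spleen"]] +
    fl$erythron[["rbc_to_spleen"]]
  influx <- influx[setdiff(names(influx), "duodenum")]
  eligible <- names(influx)[is.finite(theta[names(influx)])]
  sizes <- influx[eligible] * theta[eligible]
  if (!is.null(compartments)) {
    miss <- setdiff(compartments, names(sizes))
    if (length(miss) > 0) {
      stop("pool size not computable for: ", paste(miss, collapse = ", "))
    }
    sizes <- sizes[compartments]
  }
  sizes
}

#' Full derived-physiology report for a parameter set
#'
#' Bundles residence times, plasma-turnover shares, absolute fluxes and
#' tracer-accessible pool sizes for one diet / parameter vector.
#'
#' @inheritParams absolute_fluxes
#' @return Object of class `fk_report`: list with `residence_times`,
#'   `shares`, `fluxes`, `pool_sizes`, `plasma_pool`.
#' @export
derived_report <- function(rates, pool, topology = build_topology()) {
  structure(list(
    residence_times = residence_times(rates, topology),
    shares = plasma_shares(rates, topology),
    fluxes = absolute_fluxes(rates, pool, topology),
    pool_sizes = accessible_pool_sizes(rates, pool, topology),
    plasma_pool = pool),
    class = "fk_report")
}

#' @export
print.fk_report <- function(x, ...) {
  cat("Derived whole-body iron physiology (diet:", x$plasma_pool$diet,
      ")\n")
  cat("plasma pool:", x$plasma_pool$iron_content, "ug, total clearance",
      x$plasma_pool$total_clearance, "/day\n\n")
  cat("Plasma turnover shares (%):\n")
  print(round(100 * x$shares, 1))
  cat("\nResidence times (days):\n")
  print(round(x$residence_times, 2))
  cat("\nPlasma influx fluxes (ug/day):\n")
  print(round(x$fluxes$plasma_influx, 2))
  cat("\nErythron chain fluxes (ug/day):\n")
  print(round(x$fluxes$erythron, 2))
  cat("\nTracer-accessible pool sizes (ug):\n")
  print(round(x$pool_sizes, 1))
  invisible(x)
}

#' Write a derived report as sectioned CSV or JSON
#'
#' @param report An `fk_report`.
#' @param path Output path; extension `.json` selects JSON, otherwise a
#'   sectioned CSV (`section,name,value`) is written.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    doc <- list(
      plasma_pool = report$plasma_pool[c("diet", "iron_content",
                                         "total_clearance")],
      residence_times_days = as.list(report$residence_times),
      shares = as.list(report$shares),
      fluxes_ug_per_day = c(as.list(report$fluxes$plasma_influx),
                            as.list(report$fluxes$erythron)),
      pool_sizes_ug = as.list(report$pool_sizes))
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
    return(invisible(path))
  }
  rows <- rbind(
    data.frame(section = "residence_times",
               name = names(report$residence_times),
               value = unname(report$residence_times)),
    data.frame(section = "shares", name = names(report$shares),
               value = unname(report$shares)),
    data.frame(section = "fluxes",
               name = names(report$fluxes$plasma_influx),
               value = unname(report$fluxes$plasma_influx)),
    data.frame(section = "fluxes_erythron",
               name = names(report$fluxes$erythron),
               value = unname(report$fluxes$erythron)),
    data.frame(section = "pools", name = names(report$pool_sizes),
               value = unname(report$pool_sizes)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
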