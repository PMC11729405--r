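CATALOG_FORMAT_VERSION <- "1"

#' Save / load a behavioral catalog
#'
#' Persists a catalog as a plain-text directory bundle: `records.csv`
#' (intervention, descriptor, validity and oscillation columns),
#' `perturbations.json` (realized perturbation specs and outcomes per
#' record), and `meta.json` (space ids, provenance seeds, rollout and model
#' configuration, format version). The round trip is lossless for the
#' record table; trajectories are not stored (records are replayable from
#' the stored interventions and configuration).
#'
#' @param catalog a `grn_catalog`.
#' @param path directory to create/overwrite.
#' @return `save_catalog` returns `path` invisibly; `load_catalog` returns a
#'   `grn_catalog`.
#' @export
save_catalog <- function(catalog, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- ncol(catalog$interventions); m <- ncol(catalog$descriptors)
  num17 <- function(M) {  # shortest representation that round-trips doubles
    out <- vapply(as.numeric(M), function(v) {
      if (is.na(v)) return("NA")
      s <- sprintf("%.15g", v)
      if (as.numeric(s) == v) s else sprintf("%.17g", v)
    }, character(1))
    matrix(out, nrow = nrow(M))
  }
  rec <- data.frame(num17(catalog$interventions), num17(catalog$descriptors),
                    valid = catalog$valid, sustained = catalog$sustained)
  names(rec) <- c(paste0("i", seq_len(d)), paste0("z", seq_len(m)),
                  "valid", "sustained")
  write.csv(rec, file.path(path, "records.csv"), row.names = FALSE,
            quote = FALSE)
  sys <- catalog$system
  model_json <- if (inherits(sys$model, "grn_circuit"))
    list(type = "circuit", n = sys$model$n, W = sys$model$W, B = sys$model$B,
         tau = sys$model$tau, default_y0 = sys$model$default_y0)
  else list(type = class(sys$model)[1])
  meta <- list(format_version = CATALOG_FORMAT_VERSION,
               space_id = catalog$space_id,
               provenance = catalog$provenance,
               bspace = unclass(sys$bspace),
               ispace = unclass(sys$ispace),
               config = unclass(sys$config),
               model = model_json)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       digits = I(17), auto_unbox = TRUE, matrix = "rowmajor",
                       null = "null")
  perts <- lapply(catalog$perturbations, function(recs) {
    if (is.null(recs)) return(NULL)
    lapply(recs, function(p) {
      list(family = p$family, scale = p$scale, aux = p$aux,
           replicate = p$replicate, z = p$z, valid = p$valid,
           spec = list(family = p$spec$family, scale = p$spec$scale,
                       aux = p$spec$aux, coords = p$spec$coords,
                       window = p$spec$window, seed = p$spec$seed,
                       extent = p$spec$extent,
                       degenerate = p$spec$degenerate,
                       event_times = p$spec$events$times,
                       event_disp = p$spec$events$disp,
                       walls = p$spec$walls))
    })
  })
  jsonlite::write_json(perts, file.path(path, "perturbations.json"),
                       digits = I(17), matrix = "rowmajor", null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname save_catalog
#' @export
load_catalog <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), CATALOG_FORMAT_VERSION))
    stop("catalog format version mismatch: file has '", meta$format_version,
         "', this package reads '", CATALOG_FORMAT_VERSION, "'")
  rec <- read.csv(file.path(path, "records.csv"))
  d <- sum(grepl("^i[0-9]+$", names(rec)))
  m <- sum(grepl("^z[0-9]+$", names(rec)))
  model <- if (identical(meta$model$type, "circuit"))
    gene_circuit(matrix(as.numeric(unlist(meta$model$W)), nrow = meta$model$n,
                        byrow = !is.matrix(meta$model$W)),
                 B = meta$model$B, tau = meta$model$tau,
                 default_y0 = meta$model$default_y0)
  else NULL
  bs <- behavior_space(meta$bspace$encoder, meta$bspace$nodes,
                       meta$bspace$n_bins)
  is <- intervention_space(meta$ispace$low, meta$ispace$high,
                           meta$ispace$kind)
  cfg <- rollout_config(meta$config$T, meta$config$dt, meta$config$atol,
                        meta$config$rtol, meta$config$max_steps)
  sys <- grn_system(model, is, bs, cfg)
  catalog <- new_catalog(sys,
                         as.matrix(rec[, paste0("i", seq_len(d)), drop = FALSE]),
                         as.matrix(rec[, paste0("z", seq_len(m)), drop = FALSE]),
                         rec$valid, rec$sustained,
                         meta$provenance)
  pj <- file.path(path, "perturbations.json")
  if (file.exists(pj)) {
    perts <- jsonlite::read_json(pj, simplifyVector = FALSE)
    for (k in seq_along(perts)) {
      if (length(perts[[k]]) == 0) next
      catalog$perturbations[[k]] <- lapply(perts[[k]], function(p) {
        sp <- p$spec
        events <- NULL
        if (!is.null(sp$event_times))
          events <- list(times = unlist(sp$event_times),
                         disp = do.call(rbind, lapply(sp$event_disp, unlist)))
        walls <- if (!is.null(sp$walls))
          do.call(rbind, lapply(sp$walls, unlist)) else NULL
        z <- vapply(p$z, function(v) if (is.null(v)) NA_real_
                    else as.numeric(v), numeric(1))
        list(family = p$family, scale = p$scale, aux = p$aux,
             replicate = p$replicate, z = z, valid = p$valid,
             spec = structure(
               list(family = sp$family, scale = sp$scale, aux = sp$aux,
                    coords = unlist(sp$coords), window = sp$window,
                    events = events, walls = walls,
                    extent = unlist(sp$extent),
                    degenerate = isTRUE(sp$degenerate), seed = sp$seed),
               class = "grn_perturbation"))
      })
    }
  }
  catalog
}
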