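## Deterministic tabular outputs of the whole-particle analysis.

#' Run the full shell-analysis pipeline
#'
#' read/centre/rings/interfaces/layers/fingerprints in one call.  All steps
#' are individually exported; this wrapper fixes their composition and the
#' parameter bookkeeping for reporting.
#'
#' @param x assembly \linkS4class{StructureModel} (or a file path).
#' @param scheme a \linkS4class{DomainScheme}.
#' @param ringCutoff NTD-NTD ring contact cutoff (Angstrom).
#' @param interfaceCutoff CTD-CTD interface contact cutoff (Angstrom).
#' @param principalAxis optional axis for POLAR/LONG/LAT tags.
#' @param fingerprints also fingerprint every monomer (needs the diagnostic
#'   residues; TRUE by default).
#' @return list: centre, rings, interfaces, profile, fingerprints, params.
#' @export
analyzeShell <- function(x, scheme = domainScheme(), ringCutoff = 6.0,
                         interfaceCutoff = 5.0, principalAxis = NULL,
                         fingerprints = TRUE) {
  if (is.character(x)) x <- readStructure(x)
  centre <- particleCentre(x)
  rings <- detectRings(x, scheme, cutoff = ringCutoff, centre = centre)
  interfaces <- enumerateInterfaces(x, rings, scheme,
                                    cutoff = interfaceCutoff,
                                    principalAxis = principalAxis)
  profile <- radialProfile(x, rings, scheme)
  fp <- if (fingerprints) fingerprintAssembly(x, rings, scheme) else NULL
  list(centre = centre, rings = rings, interfaces = interfaces,
       profile = profile, fingerprints = fp,
       params = list(ringCutoff = ringCutoff,
                     interfaceCutoff = interfaceCutoff,
                     ntd = scheme@ntd, ctd = scheme@ctd,
                     marker = markerInterval(scheme),
                     groupBoundaries = c(42.5, 80),
                     groupCentres = c(20, 65, 95)))
}

#' Write analysis reports
#'
#' Emits deterministic, sorted CSV tables (interfaces, rings, layers,
#' fingerprints) and a JSON summary echoing every effective parameter.
#' Re-running on the same input produces byte-identical files.
#'
#' @param analysis result of \code{\link{analyzeShell}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written
#' @export
writeReports <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  ringDf <- do.call(rbind, lapply(analysis$rings$rings, function(r)
    data.frame(ring_id = r$id, fold = r$fold,
               chains = paste(r$chains, collapse = ";"),
               centroid_x = r$centroid[1L], centroid_y = r$centroid[2L],
               centroid_z = r$centroid[3L], radius = r$radius,
               axis_x = r$axis[1L], axis_y = r$axis[2L], axis_z = r$axis[3L],
               stringsAsFactors = FALSE)))
  wcsv(analysis$interfaces, "interfaces.csv")
  wcsv(ringDf, "rings.csv")
  wcsv(analysis$profile, "layers.csv")
  if (!is.null(analysis$fingerprints))
    wcsv(analysis$fingerprints, "fingerprints.csv")
  summary <- list(
    n_chains = sum(vapply(analysis$rings$rings, `[[`, 0L, "fold")),
    n_rings = length(analysis$rings$rings),
    n_pentamers = sum(vapply(analysis$rings$rings, `[[`, 0L, "fold") == 5L),
    n_hexamers = sum(vapply(analysis$rings$rings, `[[`, 0L, "fold") == 6L),
    n_interfaces = nrow(analysis$interfaces),
    interfaces_by_kind = as.list(table(analysis$interfaces$kind)),
    interfaces_by_group = as.list(table(analysis$interfaces$group)),
    centre = analysis$centre,
    params = analysis$params)
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[[length(paths) + 1L]] <- sp
  invisible(unlist(paths))
}
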