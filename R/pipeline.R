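#' Process one co-registered frame (quadrants + optional phase)
#'
#' The single-frame core of the pipeline: provisional cell masking,
#' reconstruction ([reconstruct_qdf()]), phase background correction,
#' watershed segmentation, per-cell dry mass, integrated DF/QDF totals,
#' per-cell means and puncta SNR.
#'
#' Signal totals are computed on the *unclipped* QDF image: clipping negative
#' residuals would rectify zero-mean noise into a positive bias growing with
#' cell area. The clipped image is used for display and for the puncta
#' threshold mask.
#'
#' @param q Raw [qdf_quadrants()].
#' @param phase Optional co-registered [qdf_phase()] (radians, raw).
#' @param reference Optional empty-field reference frame (container counts).
#' @param c_factor Numeric scaling factor or `"auto"`.
#' @param cfg A `qdf_config` (or NULL for defaults) supplying degrees,
#'   segmentation and SNR parameters.
#' @return List: `df`, `e`, `qdf`, `qdf_raw`, `labels`, `calibration`,
#'   `cells` (per-cell data frame), `noise_sd`.
#' @export
process_frame <- function(q, phase = NULL, reference = NULL,
                          c_factor = "auto", cfg = NULL) {
  cfg <- cfg %||% validate_config(list(input_dir = ".", output_dir = "."))
  ps <- cfg$pixel_size
  seg <- cfg$segmentation

  # provisional foreground for the background polynomial fit
  guide <- if (!is.null(phase)) phase$phase else
    sum_darkfield(q) / max(sum_darkfield(q))
  prelim <- .otsu_foreground(guide, seg$smooth_sigma / ps)
  prelim_mask <- .dilate_mask(prelim, seg$dilate_px)
  bg_for_fit <- if (mean(!prelim_mask) >= 0.3) !prelim_mask else NULL

  rec <- reconstruct_qdf(q, reference = reference,
                         background_mask = bg_for_fit,
                         c_factor = c_factor,
                         bit_divisor = cfg$bit_divisor,
                         degree = cfg$background_degree,
                         reference_mode = cfg$reference_mode)

  if (!is.null(phase)) {
    ph <- if (!is.null(bg_for_fit))
      correct_phase_background(phase, prelim_mask, cfg$background_degree)
    else phase
    labels <- segment_cells(ph, min_area = seg$min_area,
                            h_depth = seg$h_depth,
                            smooth_sigma = seg$smooth_sigma)
  } else {
    ph <- NULL
    # intensity fallback: watershed on normalised darkfield
    labels <- segment_cells(qdf_phase(rec$df / max(max(rec$df), 1),
                                      cfg$wavelength, ps),
                            min_area = seg$min_area, h_depth = 0.05,
                            smooth_sigma = seg$smooth_sigma)
  }

  cells <- label_centroids(labels, ps)
  tot <- per_cell_totals(rec$qdf_raw, rec$df, labels)
  cells <- merge(cells, tot[c("label", "total_df", "total_qdf")],
                 by = "label", sort = TRUE)
  cell_mask <- .dilate_mask(labels > 0, seg$dilate_px)
  bg_px <- !cell_mask
  noise_sd <- NA_real_
  cells$snr <- NA_real_
  if (sum(bg_px) >= 1000 && nrow(cells) > 0) {
    pm <- try(puncta_mask(rec$qdf, bg_px, k = cfg$snr$k, q = cfg$snr$q),
              silent = TRUE)
    if (!inherits(pm, "try-error")) {
      sn <- try(cell_snr(rec$qdf, labels, pm, bg_px), silent = TRUE)
      if (!inherits(sn, "try-error")) {
        noise_sd <- sn$noise_sd
        cells$snr <- sn$per_cell$snr[match(cells$label, sn$per_cell$label)]
      }
    }
  }
  if (!is.null(ph)) {
    dens <- density_map(ph, cfg$alpha)
    dm <- cell_dry_mass(dens, labels, ph$pixel_area)
    cells$mass_pg <- dm$mass_pg[match(cells$label, dm$label)]
    cells$mean_phase <- vapply(cells$label, function(l)
      mean(ph$phase[labels == l]), numeric(1))
  } else {
    cells$mass_pg <- NA_real_
    cells$mean_phase <- NA_real_
  }
  cells$mass_per_area <- ifelse(cells$mass_pg > 0,
                                cells$mass_pg / cells$area_um2, NA_real_)
  cells$mean_df <- ifelse(cells$area_um2 > 0,
                          cells$total_df / (cells$area_um2 / ps^2), NA_real_)
  cells$mean_qdf <- ifelse(cells$area_um2 > 0,
                           cells$total_qdf / (cells$area_um2 / ps^2), NA_real_)
  cells$df_per_mass <- ifelse(!is.na(cells$mass_pg) & cells$mass_pg > 0,
                              cells$total_df / cells$mass_pg, NA_real_)
  cells$qdf_per_mass <- ifelse(!is.na(cells$mass_pg) & cells$mass_pg > 0,
                               cells$total_qdf / cells$mass_pg, NA_real_)
  list(df = rec$df, e = rec$e, qdf = rec$qdf, qdf_raw = rec$qdf_raw,
       labels = labels, calibration = rec$calibration, cells = cells,
       noise_sd = noise_sd)
}

.otsu_foreground <- function(img, sigma_px) {
  sm <- gauss_blur(img, sigma_px)
  rng <- range(sm)
  if (diff(rng) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  norm <- (sm - rng[1]) / diff(rng)
  norm > EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
}

.dilate_mask <- function(mask, dilate_px) {
  if (!any(mask) || dilate_px <= 0) return(mask)
  kern <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), kern)) > 0.5
}

#' Run the full QDF pipeline over a directory of acquisitions
#'
#' Batch-processes a multi-position time-lapse directory laid out as
#' `pos{P}_t{T}_{TL|TR|BL|BR}.tif` quadrant frames (16-bit containers) with
#' optional `pos{P}_t{T}_phase.tif` phase images (32-bit float, stored
#' divided by 2*pi). For every frame it writes DF/E/QDF float TIFFs and a
#' label map; per position it links tracks across timepoints; the combined,
#' debris-filtered cell table and a JSON manifest are written at the end.
#' Re-running with the same configuration reproduces identical outputs (no
#' stage consumes randomness or filesystem order).
#'
#' @param config A `qdf_config` from [validate_config()], or a path/list to
#'   validate.
#' @return The run manifest (list), invisibly; the cell table is at
#'   `file.path(output_dir, "cells.csv")`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "qdf_config")) config else validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(cfg$input_dir, pattern = "^pos\\d+_t\\d+_TL\\.tif$")
  if (length(files) == 0)
    stop("no quadrant frames (pos*_t*_TL.tif) found in ", cfg$input_dir)
  key <- sub("_TL\\.tif$", "", files)
  pos <- as.integer(sub("^pos(\\d+)_t\\d+$", "\\1", key))
  tp <- as.integer(sub("^pos\\d+_t(\\d+)$", "\\1", key))
  ord <- order(pos, tp)
  key <- key[ord]; pos <- pos[ord]; tp <- tp[ord]

  reference <- if (!is.null(cfg$reference)) read_count_tiff(cfg$reference)

  read_phase_maybe <- function(k) {
    pf <- file.path(cfg$input_dir, paste0(k, "_phase.tif"))
    if (!file.exists(pf)) return(NULL)
    qdf_phase(read_float_tiff(pf, QDF_PHASE_SCALE), cfg$wavelength,
              cfg$pixel_size)
  }

  # calibration: fixed c, or least squares on the designated frame
  c_used <- cfg$c
  cal_info <- NULL
  if (identical(cfg$c, "auto")) {
    ck <- sprintf("pos%d_t%d", cfg$calibration$position,
                  cfg$calibration$timepoint)
    if (!ck %in% key)
      stop("calibration frame ", ck, " not found in input directory")
    qcal <- read_quadrants(file.path(cfg$input_dir, ck))
    fr <- process_frame(qcal, phase = read_phase_maybe(ck),
                        reference = reference, c_factor = "auto", cfg = cfg)
    cal_info <- fr$calibration
    c_used <- cal_info$c
  }

  rows <- list(); processed <- character(0); skipped <- character(0)
  for (i in seq_along(key)) {
    k <- key[i]
    qpaths <- file.path(cfg$input_dir,
                        paste0(k, "_", c("TL", "TR", "BL", "BR"), ".tif"))
    if (!all(file.exists(qpaths))) {
      skipped <- c(skipped, k)
      next
    }
    q <- read_quadrants(file.path(cfg$input_dir, k))
    fr <- process_frame(q, phase = read_phase_maybe(k),
                        reference = reference, c_factor = c_used, cfg = cfg)
    write_float_tiff(fr$df, file.path(cfg$output_dir, paste0(k, "_DF.tif")))
    write_float_tiff(fr$e, file.path(cfg$output_dir, paste0(k, "_E.tif")))
    write_float_tiff(fr$qdf, file.path(cfg$output_dir, paste0(k, "_QDF.tif")))
    write_count_tiff(fr$labels,
                     file.path(cfg$output_dir, paste0(k, "_labels.tif")))
    cells <- fr$cells
    if (nrow(cells)) {
      cells <- cbind(position = pos[i], frame = tp[i], cells)
      rows[[k]] <- cells
    }
    processed <- c(processed, k)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), frame = integer(0), label = integer(0))
  rownames(table) <- NULL

  # track linking per position across timepoints
  if (nrow(table)) {
    table$track_id <- NA_integer_
    table$track_length <- NA_integer_
    offset <- 0L
    for (p in sort(unique(table$position))) {
      sel <- table$position == p
      tr <- link_tracks(table[sel, c("frame", "label", "x_um", "y_um")],
                        max_disp = cfg$tracking$max_disp,
                        memory = cfg$tracking$memory)
      m <- match(paste(table$frame[sel], table$label[sel]),
                 paste(tr$frame, tr$label))
      tid <- tr$track_id[m] + offset
      table$track_id[sel] <- tid
      table$track_length[sel] <- as.integer(table(tid))[match(tid, sort(unique(tid)))]
      offset <- offset + max(tr$track_id, 0L)
    }
  }
  n_before <- nrow(table)
  filter_report <- NULL
  if (!is.null(cfg$debris) && nrow(table)) {
    table <- filter_debris(table, cfg$debris)
    filter_report <- attr(table, "filter_report")
  }
  utils::write.csv(table, file.path(cfg$output_dir, "cells.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "qdfim",
    version = as.character(utils::packageVersion("qdfim")),
    config = unclass(cfg),
    c_used = c_used,
    calibration = if (!is.null(cal_info)) unclass(cal_info),
    frames_processed = processed,
    frames_skipped = skipped,
    n_cells_before_filter = n_before,
    n_cells = nrow(table),
    filter_report = filter_report)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
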