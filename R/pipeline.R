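# Dataset layout, configuration and end-to-end orchestration: a cohort lives
# on disk as `cohort/<animal>/<tissue>/<eye>/...` text images plus a JSON
# manifest; `simulate_cohort()` writes a three-group synthetic cohort with
# group-dependent effect sizes calibrated to the published summaries, and
# `run_pipeline()` executes transport -> label -> nuclear localization ->
# morphometry -> statistics into a reproducible CSV/JSON report bundle.

#' Pipeline run configuration
#'
#' Serialized verbatim into every report bundle for reproducibility.
#'
#' @param transport_threshold Intact-transport threshold (fraction of the
#'   reference maximum).
#' @param n_samples Mediolateral profile bins per SC section.
#' @param grid_resolution Retinotopic map grid size per axis.
#' @param reference Reference-maximum rule (`"p99"` or `"max"`).
#' @param label_threshold Fixed intensity cut for positive immunolabel.
#' @param ctb_threshold CTB positivity cut for RGC counting.
#' @param annulus_width Perinuclear annulus width (px).
#' @param min_images_per_eye Minimum images per animal and eye for label
#'   quantification (warning below).
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(transport_threshold = 0.70, n_samples = 50,
                       grid_resolution = 100, reference = "p99",
                       label_threshold = 125, ctb_threshold = 100,
                       annulus_width = 3, min_images_per_eye = 1, seed = 1) {
  structure(
    list(transport_threshold = transport_threshold, n_samples = n_samples,
         grid_resolution = grid_resolution, reference = reference,
         label_threshold = label_threshold, ctb_threshold = ctb_threshold,
         annulus_width = annulus_width,
         min_images_per_eye = min_images_per_eye, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Deterministic hash of a configuration (31-bit polynomial over its JSON form)
#' @param config A `run_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' @keywords internal
#' @noRd
write_mask <- function(mask, path) {
  utils::write.table(mask * 1L, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' @keywords internal
#' @noRd
read_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  m == 1
}

# Group effect sizes for the simulator, calibrated to the published group
# summaries: transport deficits per eye, microbead:saline label ratios for
# the two default markers, nuclear NFKB ratios, and retinal geometry.
cohort_defaults <- function() {
  list(
    iop = list(baseline = 20.2,
               elevation = c(VEHICLE = 0.327, HE20 = 0.296, HE100 = 0.300)),
    deficit = list(SALINE = c(VEHICLE = 0.10, HE20 = 0.13, HE100 = 0.09),
                   MICROBEAD = c(VEHICLE = 0.42, HE20 = 0.27, HE100 = 0.16)),
    label_ratio = list(
      BDNF = c(VEHICLE = 2.34, HE20 = 0.71, HE100 = 1.34),
      IBA1 = c(VEHICLE = 1.29, HE20 = 0.84, HE100 = 0.86)
    ),
    label_saline_fraction = 0.10,
    nuclear_ratio = c(VEHICLE = 0.71, HE20 = 1.25, HE100 = 0.99),
    nuclear_saline_fraction = 0.50,
    retina = list(
      rt = list(SALINE = c(VEHICLE = 132.51, HE20 = 116.35, HE100 = 87.70),
                MICROBEAD = c(VEHICLE = 130.93, HE20 = 111.47, HE100 = 96.91)),
      inl = c(VEHICLE = 16.8, HE20 = 14.1, HE100 = 13.2),
      onl = c(VEHICLE = 33.6, HE20 = 33.4, HE100 = 27.1),
      rgc_density = c(VEHICLE = 3.14e-4, HE20 = 3.14e-4, HE100 = 3.16e-4)
    )
  )
}

#' Simulate a three-group cohort on disk
#'
#' Writes, for every animal, serial SC section series for both eyes (with SC
#' masks), immunolabel image pairs for the configured markers, a DAPI+NFKB
#' cell-field pair, a retinal cross-section pair, and the cohort IOP CSV;
#' group-dependent effect sizes follow the published summaries (vehicle:
#' large microbead transport deficit and elevated BDNF ratio; high dose:
#' near-saline transport). Returns the manifest, also written as
#' `manifest.json`.
#'
#' @param out_dir Output directory (created).
#' @param n_per_group Animals per treatment group.
#' @param seed Master seed; every animal derives its own sub-seed.
#' @param n_sections SC sections per eye.
#' @param image_size SC/IHC image size in pixels.
#' @param markers Immunolabel markers to render (subset of BDNF, IBA1).
#' @param n_cells Nuclei per cell field.
#' @param effects Effect-size list (see `axoquant:::cohort_defaults`); pass a
#'   modified copy to zero effects or change calibration.
#' @return The cohort manifest (class `cohort_manifest`), invisibly also on
#'   disk.
#' @export
simulate_cohort <- function(out_dir, n_per_group = 6, seed = 1,
                            n_sections = 6, image_size = c(64, 64),
                            markers = c("BDNF", "IBA1"), n_cells = 8,
                            effects = cohort_defaults()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  animals <- list()
  iop_all <- list()
  a_idx <- 0L
  for (g in GROUPS) {
    for (i in seq_len(n_per_group)) {
      a_idx <- a_idx + 1L
      id <- sprintf("%s_%02d", g, i)
      aseed <- derive_seed(seed, a_idx)
      adir <- file.path(out_dir, id)
      entry <- list(animal_id = id, group = g, files = list())

      # jitters for this animal
      jit <- with_seed(derive_seed(aseed, 1L), stats::rnorm(8, 0, 1))

      # SC transport series, both eyes
      for (eye in EYES) {
        f0 <- effects$deficit[[eye]][g]
        f <- min(max(f0 + 0.04 * jit[if (eye == "SALINE") 1 else 2], 0), 0.9)
        spec <- synthetic_spec(image_size = image_size,
                               n_sections = n_sections,
                               seed = derive_seed(aseed, 10L + match(eye, EYES)))
        ser <- generate_sc_series(spec, f, eye = eye, animal_id = id)
        pdir <- file.path(adir, "SC", eye)
        for (s in seq_along(ser$sections)) {
          write_section_image(ser$sections[[s]],
                              file.path(pdir, sprintf("sec%02d", s)))
          write_mask(ser$masks[[s]], file.path(pdir, sprintf("sec%02d_mask.tsv", s)))
        }
        entry$files[[paste0("sc_", tolower(eye))]] <-
          file.path(id, "SC", eye, sprintf("sec%02d", seq_along(ser$sections)))
        entry[[paste0("true_deficit_", tolower(eye))]] <- ser$truth$deficit_fraction
      }

      # immunolabel pairs (SC)
      for (m in markers) {
        ratio <- effects$label_ratio[[m]][g]
        base <- effects$label_saline_fraction
        fr_sal <- min(max(base * (1 + 0.10 * jit[3]), 0.01), 0.8)
        fr_mb <- min(max(fr_sal * ratio * (1 + 0.05 * jit[4]), 0.005), 0.9)
        for (eye in EYES) {
          fr <- if (eye == "SALINE") fr_sal else fr_mb
          spec <- synthetic_spec(image_size = image_size,
                                 seed = derive_seed(aseed, 20L + match(eye, EYES)))
          ihc <- generate_ihc_image(spec, fr, marker = m, tissue = "SC",
                                    eye = eye, animal_id = id,
                                    stream = match(m, markers))
          write_section_image(ihc$image,
                              file.path(adir, "SC", eye, paste0("ihc_", m)))
          entry$files[[paste0("ihc_", m, "_", tolower(eye))]] <-
            file.path(id, "SC", eye, paste0("ihc_", m))
        }
      }

      # NFKB nuclear-localization pair (SC)
      nf_sal <- min(max(effects$nuclear_saline_fraction * (1 + 0.05 * jit[5]),
                        0.05), 0.95)
      nf_mb <- min(max(nf_sal * effects$nuclear_ratio[g] * (1 + 0.05 * jit[6]),
                       0.05), 0.95)
      for (eye in EYES) {
        nf <- if (eye == "SALINE") nf_sal else nf_mb
        spec <- synthetic_spec(image_size = c(96, 96), pixel_size = 0.5,
                               noise_sd = 2,
                               seed = derive_seed(aseed, 30L + match(eye, EYES)))
        cells <- generate_nuclei_image(spec, n_cells, nf, tissue = "SC",
                                       eye = eye, animal_id = id)
        write_section_image(cells$image, file.path(adir, "SC", eye, "nfkb"))
        entry$files[[paste0("nfkb_", tolower(eye))]] <-
          file.path(id, "SC", eye, "nfkb")
      }

      # retinal cross-section pair
      for (eye in EYES) {
        rt <- effects$retina$rt[[eye]][g]
        spec <- synthetic_spec(image_size = c(64, 160), pixel_size = 1,
                               noise_sd = 2,
                               seed = derive_seed(aseed, 40L + match(eye, EYES)))
        gcl_area <- 160 * 20 # width_px * gcl band um at 1 um/px
        rgc <- max(1L, round(effects$retina$rgc_density[g] * gcl_area))
        ret <- generate_retina_section(spec, thickness_um = rt,
                                       inl_um = effects$retina$inl[g],
                                       onl_um = effects$retina$onl[g],
                                       rgc_count = rgc, n_distractors = 2,
                                       eye = eye, animal_id = id)
        pfx <- file.path(adir, "RETINA", eye, "section")
        write_section_image(ret$image, pfx)
        jsonlite::write_json(
          list(boundaries = lapply(ret$boundaries, as.list),
               truth = unclass(ret$truth)[c("layer_boundaries", "rgc_count",
                                            "n_distractors", "gcl_area_um2")]),
          paste0(pfx, "_annotation.json"), auto_unbox = TRUE, digits = NA)
        write_mask(ret$gcl_roi, paste0(pfx, "_gclroi.tsv"))
        entry$files[[paste0("retina_", tolower(eye))]] <-
          file.path(id, "RETINA", eye, "section")
      }

      # IOP series
      spec <- synthetic_spec(seed = derive_seed(aseed, 50L))
      iop <- generate_iop_series(spec, baseline_mmHg = effects$iop$baseline,
                                 elevation_fraction = effects$iop$elevation[g],
                                 animal_ids = id)
      iop$group <- g
      iop_all[[id]] <- iop
      animals[[id]] <- entry
    }
  }
  iop <- do.call(rbind, iop_all)
  rownames(iop) <- NULL
  utils::write.csv(iop, file.path(out_dir, "iop.csv"), row.names = FALSE)
  manifest <- structure(
    list(root = out_dir, animals = animals, iop_csv = "iop.csv",
         markers = markers, n_sections = n_sections, seed = seed),
    class = "cohort_manifest"
  )
  jsonlite::write_json(
    list(animals = lapply(animals, function(e) e[names(e) != "root"]),
         iop_csv = "iop.csv", markers = markers,
         n_sections = n_sections, seed = seed),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  manifest
}

#' Read and validate a cohort manifest
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return A `cohort_manifest`; errors name any referenced file that does not
#'   exist.
#' @export
read_cohort_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json in %s", dir)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  animals <- lapply(m$animals, function(e) {
    e$files <- as.list(e$files)
    e
  })
  manifest <- structure(
    list(root = dir, animals = animals, iop_csv = m$iop_csv,
         markers = m$markers, n_sections = m$n_sections, seed = m$seed),
    class = "cohort_manifest"
  )
  validate_manifest(manifest)
  manifest
}

#' @keywords internal
#' @noRd
validate_manifest <- function(manifest) {
  if (length(manifest$animals) == 0) stopf("manifest lists no animals")
  for (e in manifest$animals) {
    for (key in names(e$files)) {
      for (pfx in e$files[[key]]) {
        f <- file.path(manifest$root, paste0(pfx, ".json"))
        if (!file.exists(f)) stopf("manifest references missing file: %s", f)
      }
    }
  }
  f <- file.path(manifest$root, manifest$iop_csv)
  if (!file.exists(f)) stopf("manifest references missing file: %s", f)
  invisible(TRUE)
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes transport mapping, immunolabel quantification, nuclear
#' localization scoring, morphometry and the statistical summaries, writing a
#' deterministic CSV/JSON report bundle to `out_dir`. The bundle always
#' records the configuration and its hash; re-running with the same cohort
#' and configuration reproduces every byte.
#'
#' @param manifest A `cohort_manifest` (or a cohort directory path).
#' @param config A [run_config()].
#' @param out_dir Output directory for the report bundle.
#' @return A list with the assembled tables (`transport`, `ratios`,
#'   `morphometry`, `iop`) and the `report` list written to `report.json`.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_cohort_manifest(manifest)
  validate_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  root <- manifest$root

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # ---- transport ----
  transport <- stage("transport_mapping", {
    rows <- list()
    for (e in manifest$animals) {
      for (eye in EYES) {
        pfxs <- e$files[[paste0("sc_", tolower(eye))]]
        if (is.null(pfxs)) next
        sections <- lapply(pfxs, function(p) read_section_image(file.path(root, p)))
        masks <- lapply(pfxs, function(p) read_mask(file.path(root, paste0(p, "_mask.tsv"))))
        tr <- transport_from_sections(sections, masks,
                                      n_samples = config$n_samples,
                                      grid_resolution = config$grid_resolution,
                                      threshold = config$transport_threshold,
                                      reference = config$reference)
        rows[[paste(e$animal_id, eye)]] <- data.frame(
          animal_id = e$animal_id, group = e$group, eye = eye,
          percent_intact = tr$percent_intact, n_sections = tr$n_sections)
      }
    }
    do.call(rbind, rows)
  })

  # ---- immunolabel ----
  label_rows <- stage("immunolabel_quant", {
    rows <- list()
    for (e in manifest$animals) {
      for (m in manifest$markers) {
        for (eye in EYES) {
          pfx <- e$files[[paste0("ihc_", m, "_", tolower(eye))]]
          if (is.null(pfx)) next
          img <- read_section_image(file.path(root, pfx))
          mask <- threshold_positive_label(img, channel = m, method = "fixed",
                                           threshold = config$label_threshold)
          res <- percent_area_positive(mask, matrix(TRUE, nrow(mask), ncol(mask)),
                                       marker = m, tissue = "SC",
                                       pixel_size = img$pixel_size)
          rows[[paste(e$animal_id, m, eye)]] <- data.frame(
            animal_id = e$animal_id, group = e$group, marker = m, tissue = "SC",
            eye = eye, percent_area = res$percent_area,
            threshold = config$label_threshold)
        }
      }
    }
    do.call(rbind, rows)
  })

  # ---- nuclear localization ----
  nuclear_rows <- stage("nuclear_localization", {
    rows <- list()
    for (e in manifest$animals) {
      for (eye in EYES) {
        pfx <- e$files[[paste0("nfkb_", tolower(eye))]]
        if (is.null(pfx)) next
        img <- read_section_image(file.path(root, pfx))
        seg <- segment_nuclei(get_channel(img, "DAPI"))
        if (seg$n_nuclei == 0) next
        res <- nuclear_signal_fraction(get_channel(img, "NFKB"), seg,
                                       annulus_width = config$annulus_width)
        rows[[paste(e$animal_id, eye)]] <- data.frame(
          animal_id = e$animal_id, group = e$group, eye = eye,
          score = res$score, n_nuclei = res$n_nuclei)
      }
    }
    do.call(rbind, rows)
  })

  # ---- morphometry ----
  morpho <- stage("morphometry", {
    rows <- list()
    for (e in manifest$animals) {
      for (eye in EYES) {
        pfx <- e$files[[paste0("retina_", tolower(eye))]]
        if (is.null(pfx)) next
        img <- read_section_image(file.path(root, pfx))
        ann <- jsonlite::read_json(file.path(root, paste0(pfx, "_annotation.json")),
                                   simplifyVector = TRUE)
        boundaries <- lapply(ann$boundaries, as.data.frame)
        th <- measure_layer_thickness(boundaries, pixel_size = img$pixel_size)
        roi <- read_mask(file.path(root, paste0(pfx, "_gclroi.tsv")))
        cnt <- count_rgc_density(get_channel(img, "CTB"),
                                 get_channel(img, "DAPI"), roi,
                                 pixel_size = img$pixel_size,
                                 ctb_threshold = config$ctb_threshold)
        rows[[paste(e$animal_id, eye)]] <- data.frame(
          animal_id = e$animal_id, group = e$group, eye = eye,
          retinal_thickness_um = th$retinal_thickness_um,
          inl_thickness_um = th$inl_thickness_um,
          onl_thickness_um = th$onl_thickness_um,
          rgc_count = cnt$rgc_count, rgc_density = cnt$rgc_density)
      }
    }
    do.call(rbind, rows)
  })

  # ---- ratios + statistics ----
  stats_out <- stage("stats_reporting", {
    ratio_rows <- list()
    for (g in GROUPS) {
      for (m in manifest$markers) {
        d <- label_rows[label_rows$group == g & label_rows$marker == m, ]
        if (nrow(d) == 0) next
        long <- data.frame(animal_id = d$animal_id, eye = d$eye, value = d$percent_area)
        rs <- microbead_saline_ratio(long, group = g, marker = m, tissue = "SC")
        s <- rs$summary
        ratio_rows[[paste(g, m)]] <- data.frame(
          quantity = "label_ratio", group = g, marker = m, tissue = "SC",
          n = s$n, mean_ratio = s$mean_ratio, sem = s$sem)
      }
      if (!is.null(nuclear_rows) && nrow(nuclear_rows[nuclear_rows$group == g, ])) {
        d <- nuclear_rows[nuclear_rows$group == g, ]
        long <- data.frame(animal_id = d$animal_id, eye = d$eye, value = d$score)
        rs <- nuclear_ratio_analysis(long, group = g, tissue = "SC")
        s <- rs$summary
        ratio_rows[[paste(g, "NFKB")]] <- data.frame(
          quantity = "nuclear_ratio", group = g, marker = "NFKB", tissue = "SC",
          n = s$n, mean_ratio = s$mean_ratio, sem = s$sem)
      }
    }
    ratios <- do.call(rbind, ratio_rows)
    rownames(ratios) <- NULL

    iop <- utils::read.csv(file.path(root, manifest$iop_csv))
    elev <- iop_elevation_summary(iop)
    list(ratios = ratios, iop = elev)
  })

  # ---- write bundle ----
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wcsv(transport, "transport.csv")
  wcsv(label_rows, "label_quant.csv")
  if (!is.null(nuclear_rows)) wcsv(nuclear_rows, "nuclear.csv")
  wcsv(morpho, "morphometry.csv")
  wcsv(stats_out$ratios, "ratios.csv")
  wcsv(stats_out$iop$per_group, "iop_summary.csv")
  wcsv(stats_out$iop$elevation, "iop_elevation.csv")
  report <- list(
    config = unclass(config), config_hash = config_hash(config),
    n_animals = length(manifest$animals),
    transport_group_means = lapply(split(transport$percent_intact,
                                         paste(transport$group, transport$eye)),
                                   mean)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(transport = transport, label = label_rows, nuclear = nuclear_rows,
       morphometry = morpho, ratios = stats_out$ratios, iop = stats_out$iop,
       report = report)
}
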