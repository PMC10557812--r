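# Synthetic domain-shifted 3D phantom cohorts.
#
# The generator emulates the structure of a multi-cohort neuroimaging study at
# desk scale: an ellipsoidal "brain" partitioned into atlas regions, disease
# classes that hypointensify designated regions in proportion to a per-subject
# severity, per-domain acquisition shifts (global intensity scaling, smooth
# multiplicative bias fields, additive noise), and ordinal region-level
# pathology grades driven by the same severity.

#' Build a synthetic parcellation atlas
#'
#' Generates an ellipsoidal brain mask inside `dims` and partitions it into
#' `n_regions` contiguous regions by nearest-seed (Voronoi) assignment from
#' random interior seed points. Label 0 is background everywhere in the
#' package.
#'
#' @param dims `dim3` grid size.
#' @param n_regions Number of regions (>= 1).
#' @param seed Integer seed; the atlas is a pure function of
#'   `(dims, n_regions, seed)`.
#' @return An object of class `atlas_volume`: list with `labels` (3D integer
#'   array, 0 = background, 1..R region ids) and `region_volumes` (named
#'   integer vector, voxel count per region id).
#' @export
make_atlas <- function(dims, n_regions, seed) {
  dims <- as_dim3(dims)
  n_regions <- as.integer(n_regions)
  if (n_regions < 1) stop("make_atlas: n_regions must be >= 1")
  d <- as.integer(dims)
  ctr <- (d + 1) / 2
  semi <- 0.45 * d
  g <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  inside <- ((g$z - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$x - ctr[3]) / semi[3])^2 <= 1
  n_mask <- sum(inside)
  if (n_regions > n_mask)
    stop("make_atlas: dims too small: mask has ", n_mask,
         " voxels but n_regions = ", n_regions)
  labels <- integer(nrow(g))
  coords <- cbind(g$z, g$y, g$x)[inside, , drop = FALSE]
  seed_rows <- with_seed(seed, sample.int(n_mask, n_regions))
  seeds <- coords[seed_rows, , drop = FALSE]
  # nearest-seed assignment; on a convex mask this equals seeded Voronoi growth
  best_d <- rep(Inf, n_mask)
  best_r <- integer(n_mask)
  for (r in seq_len(n_regions)) {
    dd <- (coords[, 1] - seeds[r, 1])^2 + (coords[, 2] - seeds[r, 2])^2 +
      (coords[, 3] - seeds[r, 3])^2
    upd <- dd < best_d
    best_d[upd] <- dd[upd]
    best_r[upd] <- r
  }
  labels[inside] <- best_r
  lab_arr <- array(labels, d)
  vols <- tabulate(best_r, nbins = n_regions)
  names(vols) <- as.character(seq_len(n_regions))
  structure(list(labels = lab_arr, region_volumes = vols),
            class = "atlas_volume")
}

#' Acquisition-domain specification
#'
#' Parameters of the simulated scanner/protocol shift applied to every sample
#' of a domain: a global intensity scale, a smooth multiplicative bias field,
#' and additive Gaussian noise.
#'
#' @param name Unique domain name.
#' @param intensity_scale Positive global multiplier.
#' @param bias_field_amplitude Amplitude of the multiplicative bias field
#'   (0 disables it); the field is `1 + amplitude * smooth standard field`.
#' @param bias_field_smoothness Gaussian length-scale of the bias field, in
#'   voxels.
#' @param noise_sigma Standard deviation of additive Gaussian noise (>= 0).
#' @return A `domain_spec` list.
#' @export
domain_spec <- function(name, intensity_scale = 1, bias_field_amplitude = 0,
                        bias_field_smoothness = 8, noise_sigma = 0) {
  stopifnot(is.character(name), nchar(name) > 0,
            intensity_scale > 0, bias_field_amplitude >= 0,
            bias_field_smoothness > 0, noise_sigma >= 0)
  structure(list(name = name, intensity_scale = intensity_scale,
                 bias_field_amplitude = bias_field_amplitude,
                 bias_field_smoothness = bias_field_smoothness,
                 noise_sigma = noise_sigma), class = "domain_spec")
}

#' Phantom cohort specification
#'
#' @param dims `dim3` grid size of every volume.
#' @param n_classes Number of classes K (>= 2); class 0 is the control class
#'   and carries no disease regions.
#' @param disease_regions Named list mapping class index (as character, e.g.
#'   `"1"`) to an integer vector of atlas region ids affected by that class.
#' @param effect_size Peak signal change per unit severity (hypointensity in
#'   involved regions).
#' @param domains List of [domain_spec()] objects with unique names.
#' @param n_per_class_per_domain Subjects per (class, domain) cell.
#' @param seed Master seed for the cohort.
#' @param severity_range Range from which diseased-class severities are drawn
#'   (class 0 severity is always 0).
#' @param grade_noise Probability that a region grade is perturbed by +/- 1
#'   ordinal step (clipped to 0..3).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(dims, n_classes, disease_regions, effect_size,
                        domains, n_per_class_per_domain, seed,
                        severity_range = c(0.5, 1), grade_noise = 0) {
  dims <- as_dim3(dims)
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2, effect_size >= 0, length(domains) >= 0,
            n_per_class_per_domain >= 1, grade_noise >= 0, grade_noise <= 1)
  if (length(disease_regions)) {
    ks <- as.integer(names(disease_regions))
    if (any(is.na(ks)) || any(ks < 0) || any(ks > n_classes - 1))
      stop("cohort_spec: disease_regions keys must name classes in 0..K-1")
    if (any(ks == 0) && length(disease_regions[["0"]]))
      stop("cohort_spec: class 0 is the control class and takes no disease regions")
  }
  nm <- vapply(domains, function(d) d$name, "")
  if (anyDuplicated(nm)) stop("cohort_spec: duplicate domain names")
  structure(list(dims = dims, n_classes = n_classes,
                 disease_regions = disease_regions, effect_size = effect_size,
                 domains = domains,
                 n_per_class_per_domain = as.integer(n_per_class_per_domain),
                 seed = as.integer(seed),
                 severity_range = severity_range, grade_noise = grade_noise),
            class = "cohort_spec")
}

check_regions_exist <- function(spec, atlas) {
  all_ids <- as.integer(names(atlas$region_volumes))
  for (k in names(spec$disease_regions)) {
    miss <- setdiff(spec$disease_regions[[k]], all_ids)
    if (length(miss))
      stop("cohort_spec: class ", k, " references atlas regions not present: ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Simulate one subject's volume
#'
#' The base anatomy is a smooth seeded random field on the brain mask; voxels
#' in the label's disease regions are shifted down (hypointensity) by
#' `effect_size * severity`; the domain transform then applies, in order,
#' global intensity scaling, a smooth multiplicative bias field, additive
#' Gaussian noise, and min-max scaling to `[0, 1]`.
#'
#' @param atlas An `atlas_volume`.
#' @param spec A `cohort_spec` (dims and effect size are taken from it).
#' @param label Class label in 0..K-1; any non-control class must have disease
#'   regions in `spec`.
#' @param domain A `domain_spec`.
#' @param severity Severity in `[0, 1]`.
#' @param seed Integer seed; the sample is a pure function of its arguments.
#' @param subject_id Subject identifier string.
#' @return A `volume_sample`: list with `volume` (3D array in `[0,1]`),
#'   `label`, `domain`, `severity`, `subject_id`.
#' @export
sample_subject <- function(atlas, spec, label, domain, severity, seed,
                           subject_id = sprintf("S%06d", seed %% 1000000L)) {
  label <- as.integer(label)
  if (label < 0 || label >= spec$n_classes)
    stop("sample_subject: label ", label, " outside 0..", spec$n_classes - 1)
  if (severity < 0 || severity > 1)
    stop("sample_subject: severity must lie in [0, 1]")
  regions <- spec$disease_regions[[as.character(label)]]
  if (label != 0L && is.null(regions))
    stop("sample_subject: class ", label,
         " has no disease_regions entry; only the control class 0 may omit one")
  d <- as.integer(spec$dims)
  mask <- atlas$labels > 0
  anat_seed <- derive_seed(seed, "anatomy")
  base <- with_seed(anat_seed, array(stats::rnorm(prod(d)), d))
  base <- gaussian_smooth3(base, sigma = max(1.5, min(d) / 12))
  base <- 0.6 + 0.25 * base / max(stats::sd(base), 1e-12)
  vol <- array(0, d)
  vol[mask] <- base[mask]
  if (length(regions) && severity > 0 && spec$effect_size > 0) {
    lesion <- atlas$labels %in% regions
    dim(lesion) <- d
    vol[lesion] <- vol[lesion] - spec$effect_size * severity
  }
  # acquisition-domain transform
  vol <- vol * domain$intensity_scale
  if (domain$bias_field_amplitude > 0) {
    bf_seed <- derive_seed(seed, "bias", domain$name)
    bf <- with_seed(bf_seed, array(stats::rnorm(prod(d)), d))
    bf <- gaussian_smooth3(bf, sigma = domain$bias_field_smoothness)
    bf <- bf / max(stats::sd(bf), 1e-12)
    vol <- vol * (1 + domain$bias_field_amplitude * bf)
  }
  if (domain$noise_sigma > 0) {
    nz_seed <- derive_seed(seed, "noise", domain$name)
    vol <- vol + with_seed(nz_seed,
                           array(stats::rnorm(prod(d), sd = domain$noise_sigma), d))
  }
  vol <- minmax01(vol)
  structure(list(volume = vol, label = label, domain = domain$name,
                 severity = severity, subject_id = subject_id),
            class = "volume_sample")
}

# Equal-width quartile binning of severity x involvement into grades 0..3,
# with optional seeded +/-1 ordinal noise. Monotone in severity at noise 0.
severity_to_grade <- function(x, noise = 0, seed = NULL) {
  g <- pmin(3L, as.integer(floor(x * 4)))
  if (noise > 0 && length(g)) {
    g <- with_seed(seed, {
      flip <- stats::runif(length(g)) < noise
      step <- sample(c(-1L, 1L), length(g), replace = TRUE)
      gg <- ifelse(flip, g + step, g)
      pmax(0L, pmin(3L, gg))
    })
  }
  g
}

#' Generate a full phantom cohort with pathology grades
#'
#' Draws `n_per_class_per_domain` subjects for every (class, domain) cell.
#' Severity is 0 for the control class and uniform on `spec$severity_range`
#' for diseased classes; region grades are a monotone quartile binning of
#' `severity * involvement` with optional seeded ordinal noise. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A `cohort_spec`.
#' @param atlas An `atlas_volume` whose region ids cover `spec`'s
#'   disease regions.
#' @return List with `samples` (list of `volume_sample`) and `grades` (list of
#'   `pathology_grades`: `subject_id` plus named integer vector `grades`,
#'   one entry per atlas region).
#' @export
generate_cohort <- function(spec, atlas) {
  if (!length(spec$domains)) stop("generate_cohort: empty domain list")
  check_regions_exist(spec, atlas)
  region_ids <- as.integer(names(atlas$region_volumes))
  samples <- list()
  grades <- list()
  idx <- 0L
  for (di in seq_along(spec$domains)) {
    dom <- spec$domains[[di]]
    for (k in 0:(spec$n_classes - 1)) {
      for (i in seq_len(spec$n_per_class_per_domain)) {
        idx <- idx + 1L
        sid <- sprintf("%s_c%d_%03d", dom$name, k, i)
        sev_seed <- derive_seed(spec$seed, "severity", di, k, i)
        sev <- if (k == 0L) 0 else with_seed(sev_seed,
          stats::runif(1, spec$severity_range[1], spec$severity_range[2]))
        samp_seed <- derive_seed(spec$seed, "subject", di, k, i)
        samples[[idx]] <- sample_subject(atlas, spec, k, dom, sev, samp_seed,
                                         subject_id = sid)
        involved <- spec$disease_regions[[as.character(k)]]
        x <- ifelse(region_ids %in% involved, sev, 0)
        g_seed <- derive_seed(spec$seed, "grade", di, k, i)
        g <- severity_to_grade(x, noise = spec$grade_noise, seed = g_seed)
        names(g) <- as.character(region_ids)
        grades[[idx]] <- structure(list(subject_id = sid, grades = g),
                                   class = "pathology_grades")
      }
    }
  }
  list(samples = samples, grades = grades)
}
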