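#' Synthetic connectome cohorts
#'
#' Generates whole-brain FN/FA connectomes and subject metadata with
#' known, injectable effects, emulating the statistical structure of a
#' two-group DTI study: a mirror-symmetric small-world template, a
#' proportional right-hemisphere weight offset per group, optional nodal
#' effects, subject-level FA noise, spurious low-fiber-count edges (to be
#' removed by the FN filter), and clinical scores linearly linked to a
#' chosen region's realized asymmetry.
#'
#' @name synthetic_cohort
NULL

#' Specification for a synthetic cohort
#'
#' Defaults emulate a 49-patient / 61-control cohort on a 45-region-per-
#' hemisphere parcellation with a ring-lattice-plus-rewiring (small-world)
#' intra-hemisphere topology at density 0.30. FA weights are Beta
#' distributed with mean 0.5, typical of white-matter tracts; fiber counts
#' have mean proportional to FA. Asymmetry offsets default to zero (the
#' null generator).
#'
#' @param n_patients number of patients (group `BD`)
#' @param n_controls number of controls (group `NC`)
#' @param n_regions_per_hemisphere regions per hemisphere
#' @param edge_density target intra-hemisphere edge density in (0, 1]
#' @param rewire_prob ring-lattice rewiring probability
#' @param fa_weight_params `c(shape1, shape2)` of the Beta distribution of
#'   template FA weights
#' @param fn_mean_scale mean fiber count per unit FA
#' @param noise_sd subject-level additive FA noise (per edge)
#' @param delta_right_control proportional right-hemisphere FA offset in
#'   controls (weights multiplied by `1 + delta`)
#' @param delta_right_patient same, in patients
#' @param nodal_effects list of lists with fields `region` (abbreviation),
#'   `hemisphere`, `group`, `multiplier` applied to all FA weights
#'   incident to that node
#' @param clinical_link `NULL`, or a list with fields `region`, `metric`
#'   (currently `"Enodal"`), `slope`, `intercept`, `noise_sd`; patient
#'   YMRS scores are `intercept + slope * AS(region) + noise`, truncated
#'   at zero
#' @param spurious_edge_rate fraction of absent node pairs given a noise
#'   edge with fiber count 1-3
#' @param seed master seed; per-subject streams are derived from it by a
#'   fixed counter scheme so subjects are independent and reproducible
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_patients = 49, n_controls = 61,
                           n_regions_per_hemisphere = 45,
                           edge_density = 0.30, rewire_prob = 0.1,
                           fa_weight_params = c(6, 6),
                           fn_mean_scale = 50, noise_sd = 0.03,
                           delta_right_control = 0,
                           delta_right_patient = 0,
                           nodal_effects = NULL,
                           clinical_link = default_clinical_link(),
                           spurious_edge_rate = 0.02, seed = 1L) {
  spec <- list(n_patients = n_patients, n_controls = n_controls,
               n_regions_per_hemisphere = n_regions_per_hemisphere,
               edge_density = edge_density, rewire_prob = rewire_prob,
               fa_weight_params = fa_weight_params,
               fn_mean_scale = fn_mean_scale, noise_sd = noise_sd,
               delta_right_control = delta_right_control,
               delta_right_patient = delta_right_patient,
               nodal_effects = nodal_effects,
               clinical_link = clinical_link,
               spurious_edge_rate = spurious_edge_rate,
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
}

#' Default clinical linkage
#'
#' Links patient YMRS scores to the realized nodal-efficiency asymmetry of
#' the rolandic operculum; slope and noise are set so that the implied
#' population correlation is moderate (about 0.3) at the default FA noise
#' level, with YMRS location/spread matching a mildly symptomatic cohort.
#'
#' @param region region abbreviation, default `"ROL"`
#' @param slope YMRS points per AS unit
#' @param intercept YMRS at AS = 0
#' @param noise_sd residual YMRS standard deviation
#' @return clinical-link list for [synthetic_spec()]
#' @export
default_clinical_link <- function(region = "ROL", slope = 3,
                                  intercept = 12, noise_sd = 8) {
  list(region = region, metric = "Enodal", slope = slope,
       intercept = intercept, noise_sd = noise_sd)
}

validate_synthetic_spec <- function(spec) {
  stopifnot(spec$n_patients >= 1, spec$n_controls >= 1,
            spec$n_regions_per_hemisphere >= 2,
            spec$edge_density > 0, spec$edge_density <= 1,
            spec$noise_sd >= 0, spec$fn_mean_scale > 0,
            spec$spurious_edge_rate >= 0, spec$spurious_edge_rate <= 1,
            1 + spec$delta_right_control > 0,
            1 + spec$delta_right_patient > 0)
  for (ne in spec$nodal_effects)
    stopifnot(ne$multiplier > 0,
              ne$hemisphere %in% c("L", "R"),
              ne$group %in% c("BD", "NC"))
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate the mirror-symmetric whole-brain template
#'
#' Builds one intra-hemisphere small-world topology (ring lattice with
#' `rewire_prob` rewiring at the requested density), draws Beta FA weights
#' on its edges, copies the block identically into both hemispheres, and
#' connects every homotopic left/right pair with an inter-hemispheric edge
#' (exercising inter-hemispheric elimination downstream). Node order
#' follows the alternating L/R parcellation convention.
#'
#' @param spec a [synthetic_spec()]
#' @return a `connectome_template` list: `fa` (whole-brain FA matrix),
#'   `parcellation`, `spec`
#' @export
generate_template <- function(spec) {
  spec <- validate_synthetic_spec(spec)
  n <- spec$n_regions_per_hemisphere
  parc <- default_parcellation(n)
  set.seed(derive_seed(spec$seed, "template"))
  nei <- if (spec$edge_density >= 1) ceiling((n - 1) / 2)
         else max(1, round(spec$edge_density * (n - 1) / 2))
  g <- igraph::sample_smallworld(1, n, nei, spec$rewire_prob,
                                 loops = FALSE, multiple = FALSE)
  if (!igraph::is_connected(g))
    warning("template hemisphere graph is disconnected at density ",
            spec$edge_density, "; proceeding")
  A <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- pmin(0.99, pmax(0.01, stats::rbeta(nrow(el),
                                          spec$fa_weight_params[1],
                                          spec$fa_weight_params[2])))
  A[el] <- w
  A[el[, c(2, 1), drop = FALSE]] <- w
  N <- 2 * n
  fa <- matrix(0, N, N)
  li <- parc$index[parc$hemisphere == "L"] + 1L
  ri <- parc$index[parc$hemisphere == "R"] + 1L
  fa[li, li] <- A
  fa[ri, ri] <- A
  hw <- pmin(0.99, pmax(0.01, stats::rbeta(n, spec$fa_weight_params[1],
                                           spec$fa_weight_params[2])))
  fa[cbind(li, ri)] <- hw
  fa[cbind(ri, li)] <- hw
  structure(list(fa = fa, parcellation = parc, spec = spec),
            class = "connectome_template")
}

#' Generate one subject connectome from the template
#'
#' FA weights are the template weights times the subject's hemisphere /
#' group / nodal multipliers, plus Gaussian noise, clipped to
#' `[0.01, 1]` on the template support. Fiber counts on true edges are
#' drawn as `4 + Poisson(max(0, fn_mean_scale * FA - 4))` — mean
#' `fn_mean_scale * FA`, guaranteed to pass the default fiber-count
#' filter — and spurious noise edges with counts 1-3 are added on absent
#' pairs at `spurious_edge_rate`. Uses the RNG stream in effect at call
#' time; [generate_cohort()] seeds one stream per subject.
#'
#' @param template from [generate_template()]
#' @param group `"BD"` or `"NC"`
#' @param spec the [synthetic_spec()]
#' @param subject_id subject identifier string
#' @return a `subject_connectome` list: `subject_id`, `fn`, `fa`
#' @export
generate_subject <- function(template, group, spec,
                             subject_id = "sub-000") {
  stopifnot(group %in% c("BD", "NC"))
  parc <- template$parcellation
  N <- nrow(template$fa)
  ri <- parc$index[parc$hemisphere == "R"] + 1L
  delta <- if (group == "BD") spec$delta_right_patient
           else spec$delta_right_control
  M <- matrix(1, N, N)
  M[ri, ri] <- 1 + delta
  for (ne in spec$nodal_effects) {
    if (ne$group != group) next
    hemi_idx <- parc$index[parc$hemisphere == ne$hemisphere] + 1L
    node <- parc$index[parc$abbrev == ne$region &
                         parc$hemisphere == ne$hemisphere] + 1L
    if (length(node) != 1)
      stop("nodal effect region not in parcellation: ", ne$region)
    M[node, hemi_idx] <- M[node, hemi_idx] * ne$multiplier
    M[hemi_idx, node] <- M[hemi_idx, node] * ne$multiplier
  }
  support <- template$fa > 0
  noise <- matrix(0, N, N)
  ut <- upper.tri(noise) & support
  noise[ut] <- stats::rnorm(sum(ut), 0, spec$noise_sd)
  noise <- noise + t(noise)
  fa <- template$fa * M + noise
  fa[!support] <- 0
  fa[support] <- pmin(1, pmax(0.01, fa[support]))
  diag(fa) <- 0

  fn <- matrix(0L, N, N)
  mu <- pmax(0, spec$fn_mean_scale * fa[ut] - 4)
  cnt <- 4L + stats::rpois(sum(ut), mu)
  fn[ut] <- cnt
  # spurious low-count edges on absent pairs
  absent <- upper.tri(fn) & !support
  hit <- which(absent)[stats::runif(sum(absent)) < spec$spurious_edge_rate]
  if (length(hit)) {
    fn[hit] <- sample(1:3, length(hit), replace = TRUE)
    fa[hit] <- stats::runif(length(hit), 0.05, 0.3)
  }
  fn <- fn + t(fn)
  fa[lower.tri(fa)] <- t(fa)[lower.tri(fa)]
  structure(list(subject_id = subject_id, fn = fn, fa = fa),
            class = "subject_connectome")
}

#' Generate a full synthetic cohort
#'
#' Produces the metadata table and one connectome per subject,
#' deterministically from the master seed. Ages are drawn uniformly on the
#' group-specific ranges 22-50 (patients) and 21-49 (controls), education
#' on 11-19 / 12-19 years. Patient YMRS scores are generated from each
#' subject's realized regional asymmetry via the clinical link (if any);
#' HAMD is drawn independently. Controls carry `NA` clinical scores.
#'
#' @param spec a [synthetic_spec()]
#' @return a `synthetic_cohort` list: `metadata` (data.frame),
#'   `connectomes` (named list of `subject_connectome`), `parcellation`,
#'   `template`
#' @export
generate_cohort <- function(spec) {
  spec <- validate_synthetic_spec(spec)
  template <- generate_template(spec)
  n_tot <- spec$n_patients + spec$n_controls
  groups <- rep(c("BD", "NC"), c(spec$n_patients, spec$n_controls))
  ids <- sprintf("sub-%03d", seq_len(n_tot))

  set.seed(derive_seed(spec$seed, "metadata"))
  age <- ifelse(groups == "BD",
                sample(22:50, n_tot, replace = TRUE),
                sample(21:49, n_tot, replace = TRUE))
  gender <- ifelse(stats::runif(n_tot) < ifelse(groups == "BD",
                                                28 / 49, 32 / 61),
                   "M", "F")
  education <- ifelse(groups == "BD",
                      sample(11:19, n_tot, replace = TRUE),
                      sample(12:19, n_tot, replace = TRUE))

  connectomes <- vector("list", n_tot)
  names(connectomes) <- ids
  for (i in seq_len(n_tot)) {
    set.seed(derive_seed(spec$seed, "subject", i))
    connectomes[[i]] <- generate_subject(template, groups[i], spec, ids[i])
  }

  ymrs <- rep(NA_real_, n_tot)
  hamd <- rep(NA_real_, n_tot)
  set.seed(derive_seed(spec$seed, "clinical"))
  pat <- which(groups == "BD")
  if (length(pat)) {
    cl <- spec$clinical_link
    as_lnk <- if (is.null(cl)) rep(0, length(pat)) else
      vapply(pat, function(i)
        realized_regional_as(connectomes[[i]], template$parcellation,
                             cl$region), numeric(1))
    ic <- if (is.null(cl)) 12 else cl$intercept
    sl <- if (is.null(cl)) 0 else cl$slope
    ns <- if (is.null(cl)) 8 else cl$noise_sd
    ymrs[pat] <- pmax(0, round(ic + sl * as_lnk +
                                 stats::rnorm(length(pat), 0, ns)))
    hamd[pat] <- pmax(0, pmin(32, round(stats::rnorm(length(pat), 12, 8.4))))
  }

  metadata <- data.frame(subject_id = ids, group = groups, age = age,
                         gender = gender, education = education,
                         ymrs = ymrs, hamd = hamd,
                         stringsAsFactors = FALSE)
  structure(list(metadata = metadata, connectomes = connectomes,
                 parcellation = template$parcellation,
                 template = template),
            class = "synthetic_cohort")
}

# AS of nodal efficiency for one region of one subject, at the default
# fiber-count filter — the ground truth the clinical link conditions on.
realized_regional_as <- function(connectome, parcellation, region,
                                 threshold = 3) {
  nets <- construct_subject_networks(connectome, parcellation, threshold)
  e <- vapply(nets, function(net) {
    i <- match(region, net$node_labels)
    if (is.na(i)) stop("clinical link region not in parcellation: ", region)
    D <- shortest_paths_all(weight_to_length(net$adjacency))
    nodal_efficiency(D, i)
  }, numeric(1))
  as.numeric(asymmetry_score(e[["R"]], e[["L"]]))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf(
    "<synthetic_cohort: %d subjects (%s), %d regions per hemisphere>\n",
    nrow(x$metadata),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    nrow(x$parcellation) / 2))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Layout: `metadata.tsv` (tab-separated, header), `parcellation.tsv`,
#' and per subject `<id>_fn.tsv` / `<id>_fa.tsv` whitespace-delimited
#' square matrices without headers.
#'
#' @param dir_path output directory (created if absent)
#' @param cohort a `synthetic_cohort`, or a list with `metadata`,
#'   `connectomes` and `parcellation`
#' @return `dir_path`, invisibly
#' @export
write_cohort <- function(dir_path, cohort) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$metadata, file.path(dir_path, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohort$parcellation),
                     file.path(dir_path, "parcellation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sc in cohort$connectomes) {
    utils::write.table(sc$fn,
                       file.path(dir_path, paste0(sc$subject_id, "_fn.tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(format(sc$fa, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       file.path(dir_path, paste0(sc$subject_id, "_fa.tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir_path)
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()]. Validates that every subject listed in
#' the metadata has FN and FA matrices of the dimension implied by the
#' parcellation; errors name the offending file or subject.
#'
#' @param dir_path cohort directory
#' @return list with `metadata`, `connectomes`, `parcellation`
#' @export
read_cohort <- function(dir_path) {
  meta_path <- file.path(dir_path, "metadata.tsv")
  if (!file.exists(meta_path))
    stop("missing metadata file: ", meta_path)
  metadata <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  parc <- read_parcellation(file.path(dir_path, "parcellation.tsv"))
  N <- nrow(parc)
  connectomes <- lapply(metadata$subject_id, function(id) {
    read_mat <- function(kind) {
      p <- file.path(dir_path, paste0(id, "_", kind, ".tsv"))
      if (!file.exists(p)) stop("missing connectome file: ", p)
      m <- as.matrix(utils::read.table(p, header = FALSE))
      dimnames(m) <- NULL
      if (nrow(m) != N || ncol(m) != N)
        stop(sprintf("subject %s: %s matrix is %dx%d, expected %dx%d",
                     id, kind, nrow(m), ncol(m), N, N))
      m
    }
    structure(list(subject_id = id, fn = read_mat("fn"),
                   fa = read_mat("fa")),
              class = "subject_connectome")
  })
  names(connectomes) <- metadata$subject_id
  list(metadata = metadata, connectomes = connectomes, parcellation = parc)
}
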