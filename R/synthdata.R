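#' Generate synthetic histology tiles for one patient
#'
#' Renders tiles of eosin-pink tissue with hematoxylin-dark elliptical
#' nuclei. Nucleus centers follow a Poisson process (count `~ Poisson(lambda)`,
#' uniform positions); each nucleus is an ellipse whose expected area scales
#' as `exp(area_effect * risk)` and whose axis ratio grows with risk through
#' `ecc_base + ecc_effect * pnorm(risk)` — a monotone morphology-risk link
#' carried entirely by features the graph branch extracts (area, axis
#' lengths). The instance label mask matches the rendering exactly.
#'
#' @param n_tiles Number of tiles.
#' @param risk Latent morphology risk of the patient (standard-normal scale).
#' @param tile_size Tile side in px, >= 128 (default 160).
#' @param seed Seed; tiles are pixel-identical for identical seeds.
#' @param lambda Expected nuclei per tile (default 25).
#' @param mean_radius Baseline mean nucleus radius in px (default 6).
#' @param area_effect Log area change per unit risk (default 0.2).
#' @param ecc_base,ecc_effect Axis-ratio link parameters (defaults 1.3, 0.4).
#' @param nucleus_color,background_color RGB means (8-bit).
#' @param noise_sd Per-pixel Gaussian noise sd (default 6).
#' @param bright_fraction Fraction of rows overwritten with bright glass
#'   (default 0), for exercising tile QC.
#' @return List of [tile()] objects; each carries attributes `n_planted`
#'   (Poisson draw) and `planted` (data frame of center, semi-axes, area).
#' @export
make_tiles <- function(n_tiles, risk = 0, tile_size = 160L, seed = 1L,
                       lambda = 25, mean_radius = 6, area_effect = 0.2,
                       ecc_base = 1.3, ecc_effect = 0.4,
                       nucleus_color = c(105, 85, 160),
                       background_color = c(215, 178, 190),
                       noise_sd = 6, bright_fraction = 0) {
  stopifnot(tile_size >= 128)
  lapply(seq_len(n_tiles), function(tix) {
    with_seed(derive_seed(seed, paste0("tile", tix)), {
      n <- stats::rpois(1, lambda)
      rgb <- array(0, c(tile_size, tile_size, 3))
      for (ch in 1:3)
        rgb[, , ch] <- background_color[ch] +
          stats::rnorm(tile_size^2, 0, noise_sd)
      labels <- matrix(0L, tile_size, tile_size)
      planted <- data.frame(row = numeric(0), col = numeric(0),
                            a = numeric(0), b = numeric(0),
                            area = numeric(0))
      if (n > 0) {
        margin <- 10
        ctr_r <- stats::runif(n, margin, tile_size - margin)
        ctr_c <- stats::runif(n, margin, tile_size - margin)
        scale <- exp(area_effect * risk / 2)
        rr <- mean_radius * scale * stats::runif(n, 0.8, 1.2)
        q <- ecc_base + ecc_effect * stats::pnorm(risk)
        a <- rr * sqrt(q); b <- rr / sqrt(q)
        phi <- stats::runif(n, 0, pi)
        for (i in seq_len(n)) {
          ext <- ceiling(a[i]) + 1L
          rs <- max(1L, floor(ctr_r[i] - ext)):min(tile_size, ceiling(ctr_r[i] + ext))
          cs <- max(1L, floor(ctr_c[i] - ext)):min(tile_size, ceiling(ctr_c[i] + ext))
          dr <- outer(rs - ctr_r[i], rep(1, length(cs)))
          dc <- outer(rep(1, length(rs)), cs - ctr_c[i])
          u <- dr * cos(phi[i]) + dc * sin(phi[i])
          v <- -dr * sin(phi[i]) + dc * cos(phi[i])
          inside <- which((u / a[i])^2 + (v / b[i])^2 <= 1, arr.ind = TRUE)
          if (nrow(inside) == 0L) next
          px <- cbind(rs[inside[, 1]], cs[inside[, 2]])
          labels[px] <- i
          for (ch in 1:3)
            rgb[cbind(px, ch)] <- nucleus_color[ch] +
              stats::rnorm(nrow(px), 0, noise_sd)
        }
        planted <- data.frame(row = ctr_r, col = ctr_c, a = a, b = b,
                              area = pi * a * b)
      }
      if (bright_fraction > 0) {
        nr <- max(1L, round(bright_fraction * tile_size))
        rgb[seq_len(nr), , ] <- 248
        labels[seq_len(nr), ] <- 0L
      }
      rgb <- pmin(pmax(rgb, 0), 255)
      tl <- tile(rgb, labels)
      attr(tl, "n_planted") <- n
      attr(tl, "planted") <- planted
      tl
    })
  })
}

#' Generate a synthetic multiomics bundle with planted signal
#'
#' Expression is log-normal (log2 means uniform on `[3, 8]`, sd 1), mutation
#' Bernoulli, methylation Beta. A `causal_fraction` of features in each
#' modality is linked to the latent risk: expression log2 means shift by
#' `effects$expression * risk`, mutation and methylation logit means by the
#' corresponding effect. Causal expression features additionally differ from
#' the paired normal matrix by `de_lfc` log2 units, so the differential
#' filter can find them.
#'
#' @param n Number of tumor samples.
#' @param dims Named feature counts, e.g.
#'   `c(expression = 60, mutation = 40, methylation = 50)`.
#' @param risk Length-`n` latent omics risk.
#' @param effects Named list of per-unit-risk effect sizes (defaults 1, 1, 1).
#' @param causal_fraction Fraction of causal features per modality
#'   (default 0.25).
#' @param de_lfc Tumor-vs-normal log2 fold change planted on causal
#'   expression features (default 2).
#' @param n_normal Paired normal sample count (default `n`).
#' @param seed RNG seed.
#' @param patient_ids Optional sample ids.
#' @return List: `bundle` (an `omics_bundle`), `normal_expression`
#'   (an `omics_matrix`), `truth` (data frame: modality, feature, causal).
#' @export
make_omics <- function(n, dims = c(expression = 60, mutation = 40,
                                   methylation = 50),
                       risk = rep(0, n),
                       effects = list(expression = 1, mutation = 1,
                                      methylation = 1),
                       causal_fraction = 0.25, de_lfc = 2,
                       n_normal = n, seed = 1L, patient_ids = NULL) {
  stopifnot(all(dims > 0), length(risk) == n)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%03d", seq_len(n))
  with_seed(derive_seed(seed, "omics"), {
    n_caus <- round(causal_fraction * dims)
    n_caus[n_caus < 1] <- 1

    # expression
    pe <- dims[["expression"]]
    fe <- sprintf("gene_%03d", seq_len(pe))
    caus_e <- seq_len(n_caus[["expression"]])
    mu_e <- stats::runif(pe, 3, 8)
    shift <- matrix(0, n, pe)
    shift[, caus_e] <- de_lfc + effects$expression * risk
    expr <- 2^(matrix(mu_e, n, pe, byrow = TRUE) + shift +
                 matrix(stats::rnorm(n * pe), n, pe))
    normal <- 2^(matrix(mu_e, n_normal, pe, byrow = TRUE) +
                   matrix(stats::rnorm(n_normal * pe), n_normal, pe))

    # mutation
    pm <- dims[["mutation"]]
    fm <- sprintf("site_%03d", seq_len(pm))
    caus_m <- seq_len(n_caus[["mutation"]])
    p0 <- stats::runif(pm, 0.05, 0.95)
    logit_p <- matrix(stats::qlogis(p0), n, pm, byrow = TRUE)
    logit_p[, caus_m] <- matrix(stats::qlogis(p0[caus_m]), n, length(caus_m),
                                byrow = TRUE) + effects$mutation * risk
    mut <- matrix(stats::rbinom(n * pm, 1, stats::plogis(logit_p)), n, pm)

    # methylation (beta-values)
    pq <- dims[["methylation"]]
    fq <- sprintf("cg_%03d", seq_len(pq))
    caus_q <- seq_len(n_caus[["methylation"]])
    m0 <- stats::runif(pq, -2, 2)
    lg <- matrix(m0, n, pq, byrow = TRUE)
    lg[, caus_q] <- matrix(m0[caus_q], n, length(caus_q), byrow = TRUE) +
      effects$methylation * risk
    mm <- stats::plogis(lg)
    phi <- 30
    meth <- matrix(stats::rbeta(n * pq, mm * phi, (1 - mm) * phi), n, pq)

    bundle <- intersect_samples(
      omics_matrix(expr, "expression", patient_ids, fe),
      omics_matrix(mut, "mutation", patient_ids, fm),
      omics_matrix(meth, "methylation_beta", patient_ids, fq))
    truth <- rbind(
      data.frame(modality = "expression", feature = fe,
                 causal = seq_len(pe) %in% caus_e),
      data.frame(modality = "mutation", feature = fm,
                 causal = seq_len(pm) %in% caus_m),
      data.frame(modality = "methylation", feature = fq,
                 causal = seq_len(pq) %in% caus_q))
    list(bundle = bundle,
         normal_expression = omics_matrix(
           normal, "expression",
           sprintf("N%03d", seq_len(n_normal)), fe),
         truth = truth)
  })
}

#' Generate exponential survival records driven by a latent risk
#'
#' Event times are `Exponential(baseline_hazard * exp(beta * risk))` — the
#' proportional-hazards model the Cox loss assumes. Independent exponential
#' censoring times are calibrated (by root-finding on the expected censoring
#' probability) so the expected censored fraction matches `censor_rate`.
#'
#' @param risk Latent risk vector.
#' @param baseline_hazard Baseline event rate per day (default 1/1000).
#' @param beta Log-hazard ratio per unit risk (default 1.2).
#' @param censor_rate Target censored fraction in `[0, 1)` (default 0.3);
#'   0 disables censoring.
#' @param seed RNG seed.
#' @param patient_ids Optional ids.
#' @return Data frame: `patient_id`, `time` (days), `event` (0/1).
#' @export
make_survival <- function(risk, baseline_hazard = 1 / 1000, beta = 1.2,
                          censor_rate = 0.3, seed = 1L, patient_ids = NULL) {
  stopifnot(baseline_hazard > 0, censor_rate >= 0, censor_rate < 1)
  n <- length(risk)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%03d", seq_len(n))
  with_seed(derive_seed(seed, "survival"), {
    lam <- baseline_hazard * exp(beta * risk)
    t_evt <- stats::rexp(n, lam)
    if (censor_rate == 0) {
      return(data.frame(patient_id = patient_ids, time = t_evt, event = 1L))
    }
    # expected censored fraction with Exp(rc) censoring: mean rc/(rc + lam)
    f <- function(log_rc) mean(exp(log_rc) / (exp(log_rc) + lam)) - censor_rate
    rc <- exp(stats::uniroot(f, c(log(min(lam)) - 20, log(max(lam)) + 20))$root)
    t_cns <- stats::rexp(n, rc)
    data.frame(patient_id = patient_ids,
               time = pmin(t_evt, t_cns),
               event = as.integer(t_evt <= t_cns))
  })
}

#' Generate a complete synthetic patient cohort
#'
#' The study fixture: a latent standard-normal risk per patient, split
#' between a morphology component (driving nucleus size/eccentricity in the
#' tiles) and an omics component (driving the planted differential
#' features), with exponential survival driven by the combined risk. Ground
#' truth is stored so recovery can be measured.
#'
#' @param n Patients (default 120).
#' @param tiles_per_patient Tiles rendered per patient (default 3).
#' @param tile_size Tile side in px (default 160).
#' @param dims Omics feature counts per modality.
#' @param signal_split Relative share of risk variance carried by the image
#'   and omics components, `c(img = , omics = )`; normalized to sum to 1
#'   (default equal split).
#' @param beta Log-hazard ratio per unit combined risk (default 1.2; 0 gives
#'   a null cohort with no survival signal anywhere).
#' @param censor_rate Target censored fraction (default 0.3).
#' @param embed_dim Patch-embedding dimension for the graphs (default 8 at
#'   fixture scale).
#' @param k KNN neighbors for graph building (default 5).
#' @param build_graphs Build nuclei graphs now (default TRUE); tiles are
#'   dropped after graph construction unless `keep_tiles`.
#' @param keep_tiles Retain raw tiles on the cohort (default FALSE).
#' @param area_effect,ecc_effect Morphology-risk link strengths passed to
#'   [make_tiles()] (defaults 0.35, 0.8 — per unit of the image risk
#'   component).
#' @param omics_effects Passed to [make_omics()] as `effects`.
#' @param seed Master seed; all stages derive named sub-seeds from it.
#' @return A `cohort` object: `survival` (with clinical covariates `age`,
#'   `stage`), `omics`, `omics_truth`, `normal_expression`, `graphs`
#'   (named list of per-patient graph lists), `latent` (true risks),
#'   `params`.
#' @export
make_cohort <- function(n = 120L, tiles_per_patient = 3L, tile_size = 160L,
                        dims = c(expression = 60, mutation = 40,
                                 methylation = 50),
                        signal_split = c(img = 0.5, omics = 0.5),
                        beta = 1.2, censor_rate = 0.3,
                        embed_dim = 8L, k = 5L,
                        build_graphs = TRUE, keep_tiles = FALSE,
                        area_effect = 0.35, ecc_effect = 0.8,
                        omics_effects = list(expression = 1, mutation = 1,
                                             methylation = 1),
                        seed = 1L) {
  ids <- sprintf("P%03d", seq_len(n))
  w <- signal_split / sum(signal_split)
  latent <- with_seed(derive_seed(seed, "latent"), {
    data.frame(patient_id = ids,
               risk_img = stats::rnorm(n),
               risk_omics = stats::rnorm(n))
  })
  latent$risk <- sqrt(w[["img"]]) * latent$risk_img +
    sqrt(w[["omics"]]) * latent$risk_omics

  survival <- make_survival(latent$risk, beta = beta,
                            censor_rate = censor_rate,
                            seed = derive_seed(seed, "surv"),
                            patient_ids = ids)
  clin <- with_seed(derive_seed(seed, "clinical"), {
    stage_score <- latent$risk + stats::rnorm(n, 0, 1.5)
    data.frame(age = round(stats::rnorm(n, 60, 10)),
               stage = as.integer(cut(stage_score,
                                      stats::quantile(stage_score,
                                                      c(0, .4, .7, .9, 1)),
                                      labels = FALSE,
                                      include.lowest = TRUE)))
  })
  survival <- cbind(survival, clin)

  om <- make_omics(n, dims = dims, risk = latent$risk_omics,
                   effects = omics_effects,
                   seed = derive_seed(seed, "omics"), patient_ids = ids)

  graphs <- NULL; tiles <- NULL
  if (build_graphs || keep_tiles) {
    tiles <- lapply(seq_len(n), function(i)
      make_tiles(tiles_per_patient, risk = latent$risk_img[i],
                 tile_size = tile_size,
                 seed = derive_seed(seed, paste0("tiles", i)),
                 area_effect = area_effect, ecc_effect = ecc_effect))
    names(tiles) <- ids
  }
  if (build_graphs) {
    embed_seed <- derive_seed(seed, "embed")
    graphs <- lapply(ids, function(pid)
      lapply(seq_along(tiles[[pid]]), function(tix)
        build_graph(tiles[[pid]][[tix]], k = k, embed_dim = embed_dim,
                    seed = embed_seed,
                    tile_id = sprintf("%s_t%02d", pid, tix),
                    patient_id = pid)))
    names(graphs) <- ids
  }

  structure(list(survival = survival,
                 omics = om$bundle,
                 omics_truth = om$truth,
                 normal_expression = om$normal_expression,
                 graphs = graphs,
                 tiles = if (keep_tiles) tiles else NULL,
                 latent = latent,
                 params = list(n = n, tiles_per_patient = tiles_per_patient,
                               tile_size = tile_size, dims = dims,
                               signal_split = w, beta = beta,
                               censor_rate = censor_rate,
                               embed_dim = embed_dim, k = k, seed = seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d events, %s graphs\n",
              nrow(x$survival), sum(x$survival$event),
              if (is.null(x$graphs)) "no" else
                as.character(sum(lengths(x$graphs)))))
  invisible(x)
}

#' Tile sampling plan for a cohort
#'
#' Bookkeeping for whole-slide tile sampling: with the reference sampling of
#' 50 tiles per patient, a 679-patient cohort yields 33,950 tiles.
#'
#' @param n_patients Number of patients.
#' @param tiles_per_patient Tiles sampled per patient (default 50).
#' @return List with `n_patients`, `tiles_per_patient`, `total_tiles`.
#' @export
plan_tile_sampling <- function(n_patients, tiles_per_patient = 50L) {
  stopifnot(n_patients >= 1, tiles_per_patient >= 1)
  list(n_patients = as.integer(n_patients),
       tiles_per_patient = as.integer(tiles_per_patient),
       total_tiles = as.integer(n_patients) * as.integer(tiles_per_patient))
}
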