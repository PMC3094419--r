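# End-to-end study pipeline: generate a region, simulate the two campaigns
# (a large-area facade campaign with rural sites for the a priori background,
# and a city-style curbside campaign inside a central window), extract
# predictors in both dialects, impute sampler losses, fit both LUR models,
# validate internally (LOOCV) and across campaigns, and run the CAR-style
# comparator. Per-stage seeds are derived from a single master seed.

#' Study configuration
#'
#' Defaults emulate the two-campaign design: a 60-site facade campaign
#' (18 traffic / 34 urban background / 8 rural, plus 8 external rural sites
#' for background interpolation) sampled over 4 periods with 10.6% sampler
#' loss, and a 62-site curbside campaign (25 traffic / 37 non-traffic) inside
#' the central urban window sampled over 13 periods with 3.7% loss.
#'
#' @param region a [region_config()].
#' @param truth a [ground_truth()].
#' @param sites_large,sites_city [site_config()]s for the two campaigns.
#' @param periods_large,periods_city number of sampling periods.
#' @param missing_large,missing_city sampler-loss rates.
#' @param predictors_large,predictors_city [predictor_config()]s (coarse
#'   land-use dialect for the large area, fine dialect for the city).
#' @param m number of imputations.
#' @param delta adjusted-R^2 selection threshold (percentage points).
#' @param minimal_flow flow assigned to roads without count data.
#' @param rule a [road_class_rule()].
#' @param idw_radius,idw_power background interpolation parameters.
#' @param wind_speed regional annual mean wind speed for the CAR comparator.
#' @return a `study_config` list.
#' @export
study_config <- function(region = region_config(),
                         truth = ground_truth(),
                         sites_large = site_config(),
                         sites_city = NULL,
                         periods_large = 4, periods_city = 13,
                         missing_large = 0.106, missing_city = 0.037,
                         predictors_large = predictor_config(),
                         predictors_city = predictor_config(
                           landuse_radii = c(25, 50, 100, 250, 500)),
                         m = 10, delta = 1.0, minimal_flow = 1225,
                         rule = road_class_rule(),
                         idw_radius = 50000, idw_power = 1,
                         wind_speed = 5) {
  if (is.null(sites_city)) {
    win <- c(0.2 * region$width, 0.8 * region$width,
             0.2 * region$height, 0.8 * region$height)
    # routine-programme site selection: unlike the purpose-designed campaign,
    # traffic sites are not screened away from multi-road, high-traffic
    # situations (only a minimal 12 m guard against geometric degeneracy)
    sites_city <- site_config(counts = c(traffic = 25, urban_background = 37,
                                         rural = 0, rural_external = 0),
                              busy_exclusion = 12,
                              window = win)
  }
  structure(list(region = region, truth = truth,
                 sites_large = sites_large, sites_city = sites_city,
                 periods_large = periods_large, periods_city = periods_city,
                 missing_large = missing_large, missing_city = missing_city,
                 predictors_large = predictors_large,
                 predictors_city = predictors_city,
                 m = m, delta = delta, minimal_flow = minimal_flow,
                 rule = rule, idw_radius = idw_radius, idw_power = idw_power,
                 wind_speed = wind_speed),
            class = "study_config")
}

simulate_campaign <- function(region, config, scfg, protocol, periods, rate, seed) {
  sites <- place_sites(region, scfg, protocol, seed = derive_seed(seed, 1),
                       rule = config$rule)
  obs <- simulate_concentrations(sites, region$network, region$landuse,
                                 config$truth, periods,
                                 seed = derive_seed(seed, 2))
  apply_missingness(obs, rate, seed = derive_seed(seed, 3))
}

fit_campaign_lur <- function(y, table, a_priori, delta) {
  model <- forward_build(y, table, variable_plan(table), a_priori = a_priori,
                         delta = delta)
  backward_prune(model, delta)
}

#' Run the full two-campaign study
#'
#' Executes the whole chain: region generation, both campaigns, predictor
#' extraction in both dialects, imputation, a priori background assignment,
#' both LUR fits (with pooled coefficients across imputations), LOOCV,
#' cross-campaign validation, and the CAR-style comparator at the city-window
#' sites. Deterministic for a fixed seed.
#'
#' @param config a [study_config()].
#' @param seed master seed.
#' @param out_dir optional directory; when given, all artefacts (region files,
#'   site tables, imputed tables, predictor tables, model JSONs, validation
#'   reports, summary) are written there.
#' @return a `lur_study` list (models, reports, summary data frame).
#' @export
run_study <- function(config = study_config(), seed = 1, out_dir = NULL) {
  region <- generate_region(config$region, seed = derive_seed(seed, 10))
  camp_A <- simulate_campaign(region, config, config$sites_large, "facade",
                              config$periods_large, config$missing_large,
                              derive_seed(seed, 20))
  camp_B <- simulate_campaign(region, config, config$sites_city, "curbside",
                              config$periods_city, config$missing_city,
                              derive_seed(seed, 30))
  network_data <- assign_minimal_flow(region$network, config$minimal_flow)

  imp_A <- impute_missing(camp_A, m = config$m, seed = derive_seed(seed, 40))
  imp_B <- impute_missing(camp_B, m = config$m, seed = derive_seed(seed, 50))
  ann_A <- annual_means(imp_A)
  ann_B <- annual_means(imp_B)
  annual_A <- stats::setNames(ann_A$mean, ann_A$id)
  annual_B <- stats::setNames(ann_B$mean, ann_B$id)

  # predictor tables: each campaign in its own dialect, plus each campaign in
  # the other model's dialect for cross-campaign evaluation
  tab_AA <- build_predictor_table(camp_A, network_data, region$landuse_coarse,
                                  region$population, config$rule,
                                  config$predictors_large)
  tab_BB <- build_predictor_table(camp_B, network_data, region$landuse,
                                  region$population, config$rule,
                                  config$predictors_city)
  tab_BA <- build_predictor_table(camp_B, network_data, region$landuse_coarse,
                                  region$population, config$rule,
                                  config$predictors_large)
  tab_AB <- build_predictor_table(camp_A, network_data, region$landuse,
                                  region$population, config$rule,
                                  config$predictors_city)

  tab_AA <- assign_background(camp_A, annual_A, tab_AA,
                              config$idw_radius, config$idw_power)
  bg_B <- assign_background_external(camp_A, annual_A, camp_B,
                                     config$idw_radius, config$idw_power)
  tab_BA$background_no2 <- bg_B$background_no2[match(tab_BA$id, bg_B$id)]
  attr(tab_BA, "dictionary") <- attr(tab_AA, "dictionary")

  fit_idx_A <- camp_A$site_type != "rural_external"
  y_A <- annual_A[camp_A$id[fit_idx_A]]
  tabA_fit <- tab_AA[fit_idx_A, , drop = FALSE]
  attr(tabA_fit, "dictionary") <- attr(tab_AA, "dictionary")
  model_A <- fit_campaign_lur(y_A, tabA_fit, "background_no2", config$delta)
  y_B <- annual_B[camp_B$id]
  model_B <- fit_campaign_lur(y_B, tab_BB, character(), config$delta)

  # pooled coefficients: refit the selected variable set per imputation
  pool_A <- pool_model(model_A, imp_A, tabA_fit, fit_idx_A)
  pool_B <- pool_model(model_B, imp_B, tab_BB, rep(TRUE, nrow(tab_BB)))

  types_A <- camp_A$site_type[fit_idx_A]
  cv_A <- loocv(y_A, tabA_fit, model_A$variables, types_A)
  cv_B <- loocv(y_B, tab_BB, model_B$variables, camp_B$site_type)
  ext_A_on_B <- external_validate(model_A, y_B, tab_BA, camp_B$site_type)
  win <- config$sites_city$window
  in_win <- fit_idx_A & camp_A$x >= win[1] & camp_A$x <= win[2] &
    camp_A$y >= win[3] & camp_A$y <= win[4]
  if (sum(in_win) < 3) in_win <- fit_idx_A
  tab_AB_win <- tab_AB[in_win, , drop = FALSE]
  ext_B_on_A <- external_validate(model_B, annual_A[camp_A$id[in_win]],
                                  tab_AB_win, camp_A$site_type[in_win])

  # CAR-style comparator at the city sites and the large-area sites in the
  # city window
  bg_car_B <- stats::setNames(bg_B$background_no2, bg_B$id)
  car_in_B <- car_inputs(camp_B, network_data, bg_car_B, config$wind_speed,
                         rule = config$rule)
  car_B <- car_predict(car_in_B)
  bg_car_A <- stats::setNames(tab_AA$background_no2, tab_AA$id)
  camp_A_win <- camp_A[in_win, , drop = FALSE]
  car_in_A <- car_inputs(camp_A_win, network_data, bg_car_A[camp_A_win$id],
                         config$wind_speed, rule = config$rule)
  car_A <- car_predict(car_in_A)

  lur_at_B <- predict(model_A, tab_BA)
  ok_B <- car_B$valid
  car_vs_lur_B <- compare_predictions(lur_at_B[ok_B], car_B$total[ok_B])
  lur_at_Awin <- predict(model_A, tab_AA[in_win, , drop = FALSE])
  ok_A <- car_A$valid
  car_vs_lur_A <- compare_predictions(lur_at_Awin[ok_A], car_A$total[ok_A])
  car_obs_B <- if (sum(ok_B) >= 3)
    validation_report(y_B[ok_B], car_B$total[ok_B]) else NULL
  car_obs_A <- if (sum(ok_A) >= 3)
    validation_report(annual_A[camp_A_win$id][ok_A], car_A$total[ok_A]) else NULL

  summary_df <- data.frame(
    model = c("large_area", "large_area", "large_area",
              "city", "city", "city",
              "car_vs_lur_large_window", "car_vs_lur_city"),
    metric = c("r2_insample", "r2_loocv", "r2_external_city_sites",
               "r2_insample", "r2_loocv", "r2_external_large_sites",
               "r2_agreement", "r2_agreement"),
    value = c(model_A$r2, cv_A$r2, ext_A_on_B$r2,
              model_B$r2, cv_B$r2, ext_B_on_A$r2,
              car_vs_lur_A$r2, car_vs_lur_B$r2))

  study <- structure(list(
    region = region, camp_A = camp_A, camp_B = camp_B,
    network_data = network_data,
    tables = list(AA = tab_AA, BB = tab_BB, BA = tab_BA, AB = tab_AB),
    imputations = list(A = imp_A, B = imp_B),
    annual = list(A = annual_A, B = annual_B),
    model_large = model_A, model_city = model_B,
    pooled = list(large = pool_A, city = pool_B),
    loocv = list(large = cv_A, city = cv_B),
    external = list(large_on_city = ext_A_on_B, city_on_large = ext_B_on_A),
    car = list(city = car_B, large_window = car_A,
               agreement_city = car_vs_lur_B, agreement_large = car_vs_lur_A,
               vs_observed_city = car_obs_B, vs_observed_large = car_obs_A),
    in_window = in_win, fit_idx_A = fit_idx_A,
    summary = summary_df, config = config, seed = seed),
    class = "lur_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

# Background at sites of another campaign, interpolated from the reference
# campaign's rural sites.
assign_background_external <- function(ref_sites, ref_annual, target_sites,
                                       radius = 50000, power = 1) {
  rural_idx <- ref_sites$site_type %in% c("rural", "rural_external")
  rural <- data.frame(x = ref_sites$x[rural_idx], y = ref_sites$y[rural_idx],
                      mean = as.numeric(ref_annual[ref_sites$id[rural_idx]]))
  bg <- vapply(seq_len(nrow(target_sites)), function(i) {
    idw_background(target_sites$x[i], target_sites$y[i], rural, radius, power)$value
  }, numeric(1))
  data.frame(id = target_sites$id, background_no2 = bg, stringsAsFactors = FALSE)
}

pool_model <- function(model, campaign, table, fit_idx) {
  cols <- campaign$period_cols
  fits <- lapply(campaign$tables, function(tab) {
    y_imp <- rowMeans(as.matrix(tab[fit_idx, cols, drop = FALSE]))
    fit_ols(y_imp, table, model$variables)
  })
  dfcom <- length(fits[[1]]$residuals) - length(model$variables) - 1
  pool_estimates(fits, dfcom = dfcom)
}

#' @export
print.lur_study <- function(x, ...) {
  cat("Two-campaign LUR study (seed", x$seed, ")\n\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_roads_geojson(study$region$network, fp("roads.geojson"))
  write_ascii_grid(study$region$landuse, fp("landuse_fine.asc"))
  write_ascii_grid(study$region$landuse_coarse, fp("landuse_coarse.asc"))
  write_ascii_grid(study$region$population, fp("population.asc"))
  write_sites_csv(study$camp_A, fp("sites_large.csv"))
  write_sites_csv(study$camp_B, fp("sites_city.csv"))
  for (k in seq_len(study$imputations$A$m)) {
    write_sites_csv(study$imputations$A$tables[[k]],
                    fp(sprintf("sites_large_imp_%d.csv", k)))
  }
  write_predictor_table(study$tables$AA, fp("predictors_large.csv"))
  write_predictor_table(study$tables$BB, fp("predictors_city.csv"))
  write_lur_json(study$model_large, fp("model_large.json"))
  write_lur_json(study$model_city, fp("model_city.json"))
  jsonlite::write_json(study$pooled, fp("pooled_fits.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  utils::write.csv(study$car$city, fp("car_city.csv"), row.names = FALSE)
  utils::write.csv(study$summary, fp("summary.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Reduced-input experiments
#'
#' Re-runs the large-area fit with municipal flows replaced by the
#' minimal-flow default (limited traffic data), and the city fit with the
#' coarse land-use raster in place of the fine one (limited land-use data);
#' reports the adjusted-R^2 penalties against the full-data fits.
#'
#' @param study a `lur_study` from [run_study()].
#' @return list with the refit models and `delta_traffic`, `delta_landuse`
#'   (full minus reduced adjusted R^2, percentage-point scale).
#' @export
run_reduced_inputs <- function(study) {
  config <- study$config
  region <- study$region
  # (a) limited traffic: drop municipal counts, keep national/provincial
  net_red <- region$network
  net_red$has_count_data[net_red$authority == "municipal"] <- FALSE
  net_red <- assign_minimal_flow(net_red, config$minimal_flow)
  camp_A <- study$camp_A
  fit_idx <- study$fit_idx_A
  tab_red <- build_predictor_table(camp_A, net_red, region$landuse_coarse,
                                   region$population, config$rule,
                                   config$predictors_large)
  tab_red <- assign_background(camp_A, study$annual$A, tab_red,
                               config$idw_radius, config$idw_power)
  tab_red_fit <- tab_red[fit_idx, , drop = FALSE]
  attr(tab_red_fit, "dictionary") <- attr(tab_red, "dictionary")
  y_A <- study$annual$A[camp_A$id[fit_idx]]
  model_red_traffic <- fit_campaign_lur(y_A, tab_red_fit, "background_no2",
                                        config$delta)
  # (b) limited land use: city model on the coarse raster with the coarse radii
  camp_B <- study$camp_B
  tab_coarse <- build_predictor_table(camp_B, study$network_data,
                                      region$landuse_coarse, region$population,
                                      config$rule, config$predictors_large)
  y_B <- study$annual$B[camp_B$id]
  model_red_landuse <- fit_campaign_lur(y_B, tab_coarse, character(),
                                        config$delta)
  list(model_reduced_traffic = model_red_traffic,
       model_reduced_landuse = model_red_landuse,
       adj_r2_full_traffic = study$model_large$adj_r2,
       adj_r2_reduced_traffic = model_red_traffic$adj_r2,
       adj_r2_full_landuse = study$model_city$adj_r2,
       adj_r2_reduced_landuse = model_red_landuse$adj_r2,
       delta_traffic = 100 * (study$model_large$adj_r2 -
                                model_red_traffic$adj_r2),
       delta_landuse = 100 * (study$model_city$adj_r2 -
                                model_red_landuse$adj_r2))
}
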