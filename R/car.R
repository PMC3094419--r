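# CAR-style screening dispersion comparator: predicted concentration =
# large-scale background + local traffic contribution, with the local term
# equal to traffic emission (flow x fleet-weighted emission factor) times a
# dispersion factor that decreases with distance to the road centre and with
# wind speed, and depends on street configuration and trees. Valid only
# within 60 m of the road. All emission factors and dispersion-curve
# coefficients are documented configuration defaults chosen to satisfy the
# structural contracts (monotonicity, linearity in flow, canyon >= open);
# the module works directly in NO2-equivalent units with no NOx chemistry.

CAR_VEHICLE_CLASSES <- c("car", "van", "truck", "bus")
CAR_STREET_CONFIGS <- c("open", "one_sided_canyon", "two_sided_canyon",
                        "freeway_like")

#' Default fleet emission factors
#'
#' NO2-equivalent ug/m3 per (vehicle/24 hr) per unit dispersion factor, by
#' vehicle class and speed class. Heavy vehicles emit roughly an order of
#' magnitude more than passenger cars; stagnant urban driving is dirtier than
#' free-flowing traffic.
#'
#' @return matrix `[vehicle class, speed class]`.
#' @export
default_emission_factors <- function() {
  m <- rbind(
    car = c(urban_stagnant = 0.0048, urban_normal = 0.0035, flowing = 0.0028),
    van = c(0.0090, 0.0070, 0.0055),
    truck = c(0.0450, 0.0350, 0.0270),
    bus = c(0.0400, 0.0300, 0.0240))
  colnames(m) <- c("urban_stagnant", "urban_normal", "flowing")
  m
}

#' Default dispersion-curve coefficients per street configuration
#'
#' Each configuration has a quadratic `a d^2 + b d + c` for distances up to
#' 30 m; beyond 30 m the factor continues as `theta(30) * 30 / d` up to the
#' 60 m validity limit, continuous at 30 m. Canyon configurations sit above
#' the open-road curve at every distance.
#'
#' @return named list of coefficient vectors `c(a, b, c)`.
#' @export
default_dispersion_params <- function() {
  list(open = c(a = 0.000325, b = -0.0205, c = 0.390),
       one_sided_canyon = c(a = 0.000500, b = -0.0316, c = 0.570),
       two_sided_canyon = c(a = 0.000488, b = -0.0308, c = 0.590),
       freeway_like = c(a = 0.000310, b = -0.0190, c = 0.330))
}

#' Traffic emission rate
#'
#' Fleet-weighted emission: `flow * sum(fraction_class * EF(class, speed))`.
#' Linear in flow.
#'
#' @param flow vehicles/24 hr.
#' @param fractions named fleet shares over `car, van, truck, bus`, summing
#'   to 1.
#' @param speed_class one of the emission-factor table's speed classes.
#' @param ef emission-factor matrix, see [default_emission_factors()].
#' @return emission rate (NO2-equivalent units).
#' @export
car_emission <- function(flow, fractions, speed_class = "urban_normal",
                         ef = default_emission_factors()) {
  if (abs(sum(fractions) - 1) > 1e-6)
    stop_config("fleet fractions must sum to 1")
  if (!speed_class %in% colnames(ef))
    stop_config("unknown speed class '%s'", speed_class)
  flow * sum(fractions[CAR_VEHICLE_CLASSES] * ef[CAR_VEHICLE_CLASSES, speed_class])
}

#' Dispersion factor
#'
#' Strictly decreasing in distance (quadratic up to 30 m, then `c/d` to 60 m,
#' continuous at 30 m) and inversely proportional to wind speed (referenced
#' to a 5 m/s regional annual mean); multiplied by the tree factor.
#'
#' @param street_config one of `"open", "one_sided_canyon",
#'   "two_sided_canyon", "freeway_like"`.
#' @param distance distance to the road centre (m), in `(0, 60]`.
#' @param wind_speed regional annual mean wind speed (m/s).
#' @param tree_factor multiplier >= 1 for tree cover.
#' @param params dispersion coefficients, see [default_dispersion_params()].
#' @param wind_ref reference wind speed (m/s).
#' @return dispersion factor (s/m^2 scale).
#' @export
dispersion_factor <- function(street_config, distance, wind_speed = 5,
                              tree_factor = 1, params = default_dispersion_params(),
                              wind_ref = 5) {
  if (!street_config %in% names(params))
    stop_config("unknown street configuration '%s'", street_config)
  if (any(distance <= 0)) stop_config("distance must be > 0")
  if (any(distance > 60))
    stop_config("dispersion factor undefined beyond 60 m from the road")
  if (tree_factor < 1) stop_config("tree_factor must be >= 1")
  p <- params[[street_config]]
  quad <- function(d) p["a"] * d^2 + p["b"] * d + p["c"]
  theta30 <- quad(30)
  theta <- ifelse(distance <= 30, quad(distance), theta30 * 30 / distance)
  unname(theta * tree_factor * wind_ref / wind_speed)
}

#' CAR-style prediction
#'
#' `total = large_scale_background + emission x dispersion factor` per row.
#' Rows with `distance_to_road_center > 60` m are flagged invalid and get `NA`
#' local and total components.
#'
#' @param inputs data frame with columns `id, large_scale_background, flow,
#'   frac_car, frac_van, frac_truck, frac_bus, distance_to_road_center,
#'   speed_class, street_config, tree_factor, wind_speed`.
#' @param ef emission-factor matrix.
#' @param params dispersion coefficients.
#' @return data frame `id, background, local, total, valid`.
#' @export
car_predict <- function(inputs, ef = default_emission_factors(),
                        params = default_dispersion_params()) {
  if (any(inputs$distance_to_road_center <= 0))
    stop_config("distance_to_road_center must be > 0")
  n <- nrow(inputs)
  local <- rep(NA_real_, n)
  valid <- inputs$distance_to_road_center <= 60
  for (i in seq_len(n)) {
    if (!valid[i]) next
    fr <- c(car = inputs$frac_car[i], van = inputs$frac_van[i],
            truck = inputs$frac_truck[i], bus = inputs$frac_bus[i])
    em <- car_emission(inputs$flow[i], fr, inputs$speed_class[i], ef)
    th <- dispersion_factor(inputs$street_config[i],
                            inputs$distance_to_road_center[i],
                            inputs$wind_speed[i], inputs$tree_factor[i], params)
    local[i] <- em * th
  }
  data.frame(id = inputs$id,
             background = inputs$large_scale_background,
             local = local,
             total = inputs$large_scale_background + local,
             valid = valid,
             stringsAsFactors = FALSE)
}

#' Build CAR inputs for monitoring sites
#'
#' Takes each site's nearest road (all classes), the flow on it and a fleet
#' split derived from the heavy-duty fraction (heavy split 70/30 into trucks
#' and buses, light 85/15 into cars and vans). Distance to the road centre is
#' clamped below at the protocol-scale minimum of 3 m.
#'
#' @param sites site data frame.
#' @param network a `road_network` (data product, minimal flow assigned).
#' @param background named vector of large-scale background by site id.
#' @param wind_speed regional annual mean wind speed (m/s).
#' @param street_config,speed_class,tree_factor defaults applied to all rows.
#' @param rule a [road_class_rule()].
#' @return a CAR input data frame for [car_predict()].
#' @export
car_inputs <- function(sites, network, background, wind_speed = 5,
                       street_config = "open", speed_class = "urban_normal",
                       tree_factor = 1, rule = road_class_rule()) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    nr <- nearest_road(network, sites$x[i], sites$y[i], "all", rule)
    heavy <- if (nr$found && nr$flow > 0) nr$heavy_flow / nr$flow else 0
    data.frame(id = sites$id[i],
               large_scale_background = as.numeric(background[sites$id[i]]),
               flow = if (nr$found) nr$flow else 0,
               frac_car = 0.85 * (1 - heavy), frac_van = 0.15 * (1 - heavy),
               frac_truck = 0.7 * heavy, frac_bus = 0.3 * heavy,
               distance_to_road_center = max(3, nr$distance),
               speed_class = speed_class, street_config = street_config,
               tree_factor = tree_factor, wind_speed = wind_speed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
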