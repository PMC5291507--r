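# Robot/arena defaults shared by the R helpers and the compiled loop.
.robot_defaults <- function() {
  list(
    arena_side = 1000, robot_radius = 25, speed_px_ms = 1,
    sensor_angle = pi / 4, sensor_range = 80, turn_per_spike = pi / 6,
    min_distance = 1, sensitivity = 8, duration_ms = 1000000L,
    traj_every_ms = 100L, hull_based = TRUE
  )
}

#' Ray distance from a point to the square arena boundary
#'
#' Length of the ray from `(x, y)` along direction `theta` (radians, standard
#' mathematical orientation) to the boundary of the square `[0, side]^2`.
#'
#' @param x,y Position inside the arena (px).
#' @param theta Ray direction (radians).
#' @param side Arena side length (px).
#' @return Distance in px.
#' @export
#' @examples
#' ray_distance(500, 500, 0)      # 500 px to the right wall
ray_distance <- function(x, y, theta, side = 1000) {
  .ray_to_wall_cpp(x, y, theta, side)
}

#' Read the robot's two distance sensors
#'
#' Each sensor casts a single ray from the robot's centre at `+-sensor_angle`
#' from the heading; the reported distance is the ray length minus the robot
#' `radius` (hull-based, so the reading spans its full range down to wall
#' contact; pass `radius = 0` for a centre-based reading). A sensor is active
#' when its distance is at most `sensor_range`; its per-millisecond input to
#' the corresponding network input zone is then `sensitivity / distance` mV
#' (the distance is clamped at `min_distance` px to keep the input finite
#' against a touching wall).
#'
#' @param x,y,heading Robot pose.
#' @param sensitivity Sensor gain in mV (default 8).
#' @param side Arena side (px).
#' @param radius Robot radius subtracted from the ray length (default 25).
#' @param sensor_angle Sensor offset from heading (default pi/4).
#' @param sensor_range Activation range in px (default 80).
#' @param min_distance Distance clamp in px (default 1).
#' @return A tibble with rows `left`/`right` and columns `sensor`, `distance`,
#'   `input_mv`.
#' @export
#' @examples
#' sense(960, 500, 0)   # right wall 40 px ahead of the centre
sense <- function(x, y, heading, sensitivity = 8, side = 1000, radius = 25,
                  sensor_angle = pi / 4, sensor_range = 80,
                  min_distance = 1) {
  dl <- ray_distance(x, y, heading + sensor_angle, side) - radius
  dr <- ray_distance(x, y, heading - sensor_angle, side) - radius
  inp <- function(d) {
    if (d <= sensor_range) sensitivity / max(d, min_distance) else 0
  }
  tibble(
    sensor = c("left", "right"),
    distance = c(dl, dr),
    input_mv = c(inp(dl), inp(dr))
  )
}

#' Steer and advance the robot by one millisecond
#'
#' Non-differential steering: the heading turns `+turn_per_spike` radians per
#' spike in the left output zone and `-turn_per_spike` per spike in the right
#' output zone; the robot then advances `speed` px along the new heading. On
#' wall contact the position is clamped component-wise to
#' `[radius, side - radius]` (motion stops; the heading is unchanged).
#'
#' @param robot A list or one-row tibble with `x`, `y`, `heading`.
#' @param n_left,n_right Spike counts of the two output zones this
#'   millisecond.
#' @param turn_per_spike Turn per spike in radians (default pi/6).
#' @param speed Speed in px/ms (default 1).
#' @param side Arena side (px).
#' @param radius Robot radius (px).
#' @return The updated pose list.
#' @export
#' @examples
#' steer_and_move(list(x = 500, y = 500, heading = 0), n_left = 2, n_right = 1)
steer_and_move <- function(robot, n_left, n_right, turn_per_spike = pi / 6,
                           speed = 1, side = 1000, radius = 25) {
  heading <- robot$heading + turn_per_spike * (n_left - n_right)
  x <- robot$x + speed * cos(heading)
  y <- robot$y + speed * sin(heading)
  list(
    x = min(max(x, radius), side - radius),
    y = min(max(y, radius), side - radius),
    heading = heading
  )
}

#' Simulate embodied wall-avoidance learning
#'
#' A simulated robot moves in a square arena while a 100-neuron spiking
#' network with STDP and short-term plasticity steers it. In closed loop, the
#' two distance sensors stimulate the two input zones with
#' `sensitivity / distance` mV whenever a wall is within sensor range, so
#' steering away from walls removes the stimulation at exactly the right
#' timing - the condition for stimulation-avoidance learning. Controls:
#' `"open"` applies a constant `const_amplitude` mV to both input zones
#' regardless of the robot's pose; `"matched_open"` is open loop with the
#' per-channel amplitude chosen by the caller (typically half the mean per-ms
#' stimulation measured in matched closed-loop runs).
#'
#' The stimulation ledger is accounted per sensor channel: an open-loop run at
#' 8 mV on each of the two channels delivers 16 mV per millisecond.
#'
#' @param mode `"closed"`, `"open"` or `"matched_open"`.
#' @param sensitivity Sensor gain in mV (closed loop; default 8).
#' @param const_amplitude Per-channel constant amplitude in mV (open-loop
#'   modes; default 8).
#' @param duration_ms Simulated duration (default 1,000,000 ms = 1000 s).
#' @param seed Master seed; controls network, zones, initial pose and noise.
#' @param config Network/plasticity configuration; defaults to the
#'   fully-connected STP network (w_max 20, sigma 3, no decay).
#' @param traj_every_ms Trajectory sampling interval (default 100).
#' @return An object of class `lsa_robot_run`: `trajectory` tibble (sampled),
#'   per-ms `near_wall` and `stim_mv` vectors, `cumulative_stimulation`,
#'   `config`, `seed`. See [wall_proximity()], [mean_stimulation()].
#' @export
#' @examples
#' run <- simulate_robot("closed", duration_ms = 2000, seed = 1)
#' glance(run)
simulate_robot <- function(mode = c("closed", "open", "matched_open"),
                           sensitivity = 8, const_amplitude = 8,
                           duration_ms = 1000000, seed = 1,
                           config = NULL, traj_every_ms = 100) {
  mode <- match.arg(mode)
  if (is.null(config)) {
    config <- lsa_config(
      "stp_selective",
      decay_mu = 0, forbid_direct_io = FALSE,
      zone_sizes = c(input_left = 10, input_right = 10,
                     output_left = 10, output_right = 10)
    )
  }
  stopifnot(inherits(config, "lsa_config"))
  rb <- .robot_defaults()
  rb$sensitivity <- sensitivity
  rb$duration_ms <- as.integer(duration_ms)
  rb$traj_every_ms <- as.integer(traj_every_ms)

  network <- .build_from_config(config, seed)
  set.seed(seed_for(seed, "pose"))
  x0 <- runif(1, 100, rb$arena_side - 100)
  y0 <- runif(1, 100, rb$arena_side - 100)
  heading0 <- runif(1, 0, 2 * pi)

  robot <- list(
    mode = mode, sensitivity = rb$sensitivity,
    const_amplitude = const_amplitude,
    zone_in_left = .zone0(network$zones, "input_left"),
    zone_in_right = .zone0(network$zones, "input_right"),
    zone_out_left = .zone0(network$zones, "output_left"),
    zone_out_right = .zone0(network$zones, "output_right"),
    side = rb$arena_side, radius = rb$robot_radius, speed = rb$speed_px_ms,
    sensor_range = rb$sensor_range, sensor_angle = rb$sensor_angle,
    turn_per_spike = rb$turn_per_spike, min_distance = rb$min_distance,
    x0 = x0, y0 = y0, heading0 = heading0, hull_based = rb$hull_based,
    duration_ms = rb$duration_ms, traj_every_ms = rb$traj_every_ms
  )
  nn <- network$neurons
  set.seed(seed_for(seed, "run"))
  out <- .run_robot_cpp(t(network$weights), t(network$exists), network$n_exc,
                        nn$a, nn$b, nn$c, nn$d, nn$v, nn$u,
                        .dyn_list(config), robot)
  traj <- as_tibble(as.data.frame(out$trajectory))
  names(traj) <- c("time_ms", "x", "y", "heading", "dist_left", "dist_right",
                   "stim_mv_this_ms")
  off <- if (isTRUE(rb$hull_based)) rb$robot_radius else 0
  traj$near_wall_flag <- pmin(
    pmin(traj$x, rb$arena_side - traj$x),
    pmin(traj$y, rb$arena_side - traj$y)) - off < rb$sensor_range
  structure(
    list(
      mode = mode, trajectory = traj,
      near_wall = as.logical(out$near_wall),
      stim_mv = as.numeric(out$stim_mv),
      cumulative_stimulation = out$cumulative_stimulation,
      w_final = t(out$w_final), final_pose = out$final_pose,
      network = network, config = config, seed = seed,
      sensitivity = sensitivity, const_amplitude = const_amplitude,
      duration_ms = as.integer(duration_ms), arena = rb
    ),
    class = "lsa_robot_run"
  )
}

#' Fraction of time spent near a wall
#'
#' Fraction of milliseconds in `[from_s, to_s)` during which the robot's
#' centre is within `sensor_range` (80 px) of any wall.
#'
#' @param run An `lsa_robot_run`.
#' @param from_s,to_s Window bounds in seconds (defaults: whole run).
#' @return A fraction in `[0, 1]`.
#' @export
wall_proximity <- function(run, from_s = 0, to_s = run$duration_ms / 1000) {
  stopifnot(inherits(run, "lsa_robot_run"))
  idx <- seq(from_s * 1000 + 1, min(to_s * 1000, run$duration_ms))
  mean(run$near_wall[idx])
}

#' Mean delivered stimulation per millisecond
#'
#' Average of the per-channel stimulation ledger over a time window
#' (mV per ms, summed over the two sensor channels).
#'
#' @inheritParams wall_proximity
#' @return Mean stimulation in mV/ms.
#' @export
mean_stimulation <- function(run, from_s = 0, to_s = run$duration_ms / 1000) {
  stopifnot(inherits(run, "lsa_robot_run"))
  idx <- seq(from_s * 1000 + 1, min(to_s * 1000, run$duration_ms))
  mean(run$stim_mv[idx])
}

#' @export
print.lsa_robot_run <- function(x, ...) {
  cat(sprintf("<lsa_robot_run> %s loop, %g s, seed %s\n",
              x$mode, x$duration_ms / 1000, format(x$seed)))
  cat(sprintf("  wall proximity: %.1f%% overall, %.1f%% final 300 s\n",
              100 * wall_proximity(x),
              100 * wall_proximity(x, max(0, x$duration_ms / 1000 - 300))))
  cat(sprintf("  stimulation: %.3f mV/ms on average\n", mean(x$stim_mv)))
  invisible(x)
}

#' @rdname simulate_robot
#' @param x An `lsa_robot_run`.
#' @param ... Unused.
#' @export
tidy.lsa_robot_run <- function(x, ...) x$trajectory

#' @rdname simulate_robot
#' @export
glance.lsa_robot_run <- function(x, ...) {
  dur_s <- x$duration_ms / 1000
  tibble(
    mode = x$mode,
    seed = x$seed,
    duration_s = dur_s,
    sensitivity_mv = x$sensitivity,
    wall_proximity = wall_proximity(x),
    wall_proximity_final_300s = wall_proximity(x, max(0, dur_s - 300)),
    mean_stim_mv_ms = mean(x$stim_mv),
    cumulative_stimulation_mv = x$cumulative_stimulation
  )
}
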