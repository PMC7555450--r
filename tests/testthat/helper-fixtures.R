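# Small, fast simulator parameter sets used across tests.
small_params <- function(...) {
  args <- list(fragment_diameter = 80,
               voxel_size = c(dx = 4, dy = 4, dz = 10),
               time_points = c(0, 12, 24),
               perimeter_damage_depth = 4,
               kill_front_speed = 0.5,
               dying_duration = 18,
               til_surface_rate = 2e-5,
               shape_perturbation = 0.05,
               seed = 1L)
  do.call(simulation_params, modifyList(args, list(...)))
}

# A stack built directly from arrays (no simulator), handy for IO and
# classification unit tests.
toy_stack <- function(nz = 2, ny = 4, nx = 5, fill = 0, time_h = 0,
                      fragment_id = "toy") {
  mk <- function(v) array(v, dim = c(nz, ny, nx))
  channel_stack(list(live_green = mk(fill), til_red = mk(fill),
                     dead_apc = mk(fill)),
                voxel_size = c(dx = 2, dy = 2, dz = 10),
                time_h = time_h, fragment_id = fragment_id)
}

# classified_volume with prescribed per-class voxel counts (grid is a flat
# row of voxels; geometry is irrelevant to the fraction arithmetic).
classified_from_counts <- function(counts, voxel_size = c(dx = 1, dy = 1,
                                                          dz = 1),
                                   fragment_id = "synthetic", time_h = 0) {
  labels <- rep(match(names(counts), TK_CLASSES), counts)
  n <- length(labels)
  masks <- list(
    live_green = array(TK_CLASSES[labels] %in%
                         c("live", "dying", "til_on_live"), c(1, 1, n)),
    til_red = array(TK_CLASSES[labels] %in%
                      c("til", "dying_til", "til_on_live"), c(1, 1, n)),
    dead_apc = array(TK_CLASSES[labels] %in%
                       c("dead", "dying", "dying_til"), c(1, 1, n)))
  classify_voxels(masks, voxel_size, fragment_id = fragment_id,
                  time_h = time_h)
}

# Minimal experiment layout without any stack files on disk.
toy_layout <- function(fragments, time_points = c(0, 24)) {
  tilkill:::validate_layout(list(
    time_points = time_points,
    fragments = lapply(seq_len(nrow(fragments)), function(i)
      list(fragment_id = fragments$fragment_id[i],
           condition = fragments$condition[i]))))
}

write_layout_yaml <- function(path, fragments, time_points = c(0, 24),
                              conditions = NULL) {
  frs <- lapply(seq_len(nrow(fragments)), function(i)
    list(fragment_id = fragments$fragment_id[i],
         condition = fragments$condition[i]))
  cfg <- list(time_points = time_points, fragments = frs)
  if (!is.null(conditions)) cfg$conditions <- conditions
  yaml::write_yaml(cfg, path)
  path
}
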