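mode: simulate
seed: 1
output_dir: proximap-out
simulate:
  model:
    geometry:
      ribbon_length: 5600.0
      ribbon_width: 20.0
      curvature: 0.0
      stack_axis:
      - 0.0
      - 1.0
      field_of_view:
      - 6000.0
      - 6000.0
      segments: 8
      face_extent: 300.0
    layouts:
      GM130:
        target_id: GM130
        kind: layer
        axial_offset: 0.0
        site_density: 4000.0
      GRASP65:
        target_id: GRASP65
        kind: layer
        axial_offset: 15.0
        site_density: 4000.0
      Giantin:
        target_id: Giantin
        kind: layer
        axial_offset: 90.0
        site_density: 4000.0
      GALNT2:
        target_id: GALNT2
        kind: layer
        axial_offset: 110.0
        site_density: 4000.0
      Rab6:
        target_id: Rab6
        kind: layer
        axial_offset: 130.0
        site_density: 4000.0
      Golgin97:
        target_id: Golgin97
        kind: layer
        axial_offset: 190.0
        site_density: 4000.0
      TGN46:
        target_id: TGN46
        kind: layer
        axial_offset: 210.0
        site_density: 4000.0
      VPS13B:
        target_id: VPS13B
        kind: interface_puncta
        axial_offset: 35.0
        site_density: 5000.0
        puncta_count: 20
        puncta_radius: 40.0
  acquisition:
    round_order:
    - GM130
    - GRASP65
    - Giantin
    - GALNT2
    - Rab6
    - Golgin97
    - TGN46
    - VPS13B
    mean_blinks_per_site: 5.0
    blink_count_law: poisson
    sigma_loc: 5.0
    linkage_radius: 10.0
    false_rate: 25.0
    erasure_efficiency: 0.995
    round_shifts: ~
    pixel_size: 108.0
    n_frames: 30000.0
    mean_event_frames: 3.0
alignment:
  enabled: yes
  reference: ~
  bin_size: 10.0
  max_shift: 500.0
proximity:
  cutoff: 500.0
  symmetrize: no
  min_pair_count: 50.0
precision:
  fit_range: 100.0
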