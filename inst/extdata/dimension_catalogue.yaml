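# Indicator catalogue used to instruct an external image-auditing model.
# Three groups: indoor, outdoor, and a free dimension for salient features
# not covered by the named indicators.
dimensions:
  - group: indoor
    name: daylighting_and_lighting
    indicators: "Window orientation and area; number and color temperature of luminaires; blackout or shading curtains."
  - group: indoor
    name: ventilation_and_air_quality
    indicators: "Operable doors and windows; mechanical ventilation or air-purification devices."
  - group: indoor
    name: spatial_layout_and_privacy
    indicators: "Open-plan versus compartmentalized functional zones; corridor length; extent of visual exposure and sightlines."
  - group: indoor
    name: safety_and_assistive_features
    indicators: "Bathroom grab bars; corridor lighting; handrail-wall luminance contrast; wayfinding signage; nurse-call buttons."
  - group: indoor
    name: spatial_capacity
    indicators: "Overall spaciousness; wheelchair accessibility and maneuvering clearance."
  - group: indoor
    name: comfortable_flexible_furniture
    indicators: "Relative placement of beds to windows and desks; social seating configurations."
  - group: indoor
    name: aesthetics_and_art
    indicators: "Decorative objects and style; indoor plants; proportion of timber; material reflectance; color palette and saturation."
  - group: outdoor
    name: greening_and_natural_elements
    indicators: "Vegetation coverage; species richness and health; water features."
  - group: outdoor
    name: accessible_design_and_facilities
    indicators: "Entrances and site boundaries; fencing; handrails; sidewalk and path width; outdoor furniture; color contrast."
  - group: outdoor
    name: main_building_design
    indicators: "Facade articulation and complexity; architectural style; materials; color scheme; visual interest."
  - group: outdoor
    name: entrance_forecourt_and_seating
    indicators: "Seating in the entrance plaza; steps; landscape ornaments; scale and proportions."
  - group: outdoor
    name: paths_and_surface_conditions
    indicators: "Walkway width; paving materials; diversity of route types."
  - group: outdoor
    name: shade_and_shelter
    indicators: "Shaded or rain pavilions; terraces; overhead canopies."
  - group: outdoor
    name: visibility_and_night_lighting
    indicators: "Pedestrian-path and facade lighting provision."
  - group: outdoor
    name: proximity_and_activity_intensity
    indicators: "Connectivity to commercial streets; openness; streetscape vibrancy; access to public services."
  - group: outdoor
    name: environmental_quality
    indicators: "Cleanliness and maintenance; condition of facilities; orderliness."
  - group: outdoor
    name: social_opportunities
    indicators: "Activity and interaction amenities; furniture for gathering; family-visit and group-activity facilities."
  - group: free
    name: free_dimension
    indicators: "Any salient environmental attribute not covered above, for example cultural symbols, pet-friendly amenities, digital devices or displays, or specialized activity rooms."
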