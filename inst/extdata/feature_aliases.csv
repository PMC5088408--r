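field,alias,canonical
nuclear_shape,potato-shaped,potato
nuclear_shape,ovoid with shallow concavities,potato
nuclear_shape,comma-shaped,comma
euchromatin_texture,dark blue,dark_obscured
euchromatin_texture,light blue,light_homogeneous
euchromatin_texture,watery,light_watery
euchromatin_texture,empty,empty_unstained
cytoplasm_rim,thick rim,continuous_thick
cytoplasm_rim,thin rim,continuous_thin
nucleus_stain,darkly stained,dark
nucleus_stain,lightly stained,light
nucleolus,large,prominent_large
nucleolus,not visible,not_visible
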