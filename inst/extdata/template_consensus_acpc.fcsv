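# Markups fiducial file version = 4.11
# CoordinateSystem = RAS
# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID
vtkMRMLMarkupsFiducialNode_1,-0.24,1.88,-4.75,0,0,0,1,1,1,0,AC,anterior commissure,
vtkMRMLMarkupsFiducialNode_2,-0.06,-24.68,-2.36,0,0,0,1,1,1,0,PC,posterior commissure,
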